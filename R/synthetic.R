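# Small stoichiometric networks with known analytic properties.
# All randomness here is confined to make_random_feasible and is
# reproducible from a single integer seed; the other generators are frozen.

#' Linear chain toy model
#'
#' `EX_A` (uptake bound) feeding a chain of `n_steps` conversions into
#' `EX_Z`. The optimum of any objective along the chain is the uptake bound
#' and is unique, which makes the model a fixture for FBA/FVA identities.
#'
#' @param n_steps Number of interior conversions (>= 1).
#' @param uptake_bound Maximal uptake of the substrate (mmol/gDW/h).
#' @return A [metabolic_model()] with objective `EX_Z`.
#' @export
make_linear_chain <- function(n_steps, uptake_bound) {
  stopifnot(n_steps >= 1, uptake_bound >= 0)
  met_ids <- paste0("m", seq_len(n_steps + 1L), "_c")
  mets <- do.call(rbind, lapply(met_ids, function(id)
    metabolite(id, formula = "C")))
  rxns <- c(
    list(reaction("EX_A", stats::setNames(-1, met_ids[1]),
                  lb = -uptake_bound, ub = 1000,
                  name = "substrate exchange", gene_associated = FALSE)),
    lapply(seq_len(n_steps), function(k)
      reaction(paste0("R", k),
               stats::setNames(c(-1, 1), met_ids[c(k, k + 1L)]),
               lb = 0, ub = 1000, gene_associated = TRUE)),
    list(reaction("EX_Z", stats::setNames(-1, met_ids[n_steps + 1L]),
                  lb = 0, ub = 1000, name = "product exchange",
                  gene_associated = FALSE)))
  metabolic_model(mets, rxns, objective = c(EX_Z = 1),
                  annotations = list(model_id = sprintf("chain_%d", n_steps)))
}

#' Phototroph toy model with closed-form optima
#'
#' A frozen ~20-reaction emulation of light-limited photoautotrophic
#' metabolism: a photon exchange capped at 45 mmol/gDW/h, linear electron
#' flow (`LEF`) producing ATP and NADPH at the 1.28 stoichiometric ratio,
#' cyclic electron flow (`CEF`) producing ATP only, CO2 fixation (`CBB`, 3
#' ATP + 2 NADPH per carbon), a biomass drain (1 carbon + 1.5 ATP + 0.5
#' NADPH per unit), a two-carbon product route with its own cofactor demand
#' (`PROD`, 2 ATP + 2 NADPH on top of fixation), an ATP maintenance drain,
#' and an NADH leg (catabolism + transhydrogenase) that optimization leaves
#' inactive. Loaded from a shipped native-dialect fixture so the
#' hand-derived constants below stay valid.
#'
#' Closed forms (derived once from the stoichiometry): photon cost is
#' 3.8 per biomass unit and 6.32 per product unit, so with 45 photons
#' `mu_max = 45/3.8`, `P_max = 45/6.32`, the phase-plane frontier is the
#' line `3.8*mu + 6.32*v = 45`, and at biomass fraction f the two-step
#' product flux is `(1-f)*P_max`. At the biomass optimum the ATP and NADPH
#' flux-sums are `4.5*mu_max` and `2.5*mu_max` (ratio 1.8) and the NADH
#' flux-sum is 0.
#'
#' @return A [metabolic_model()].
#' @export
make_phototroph_toy <- function() {
  read_model(system.file("extdata", "fixtures", "phototroph_toy",
                         package = "cyanoflux"))
}

#' Closed-form reference values for [make_phototroph_toy()]
#'
#' @return Named list: `mu_max`, `p_max`, `photon_per_biomass`,
#'   `photon_per_product`, `atp_flux_sum`, `nadph_flux_sum`,
#'   `nadh_flux_sum`, `atp_nadph_ratio` (the flux-sums at the biomass
#'   optimum).
#' @export
phototroph_toy_constants <- function() {
  mu_max <- 45 / 3.8
  list(mu_max = mu_max,
       p_max = 45 / 6.32,
       photon_per_biomass = 3.8,
       photon_per_product = 6.32,
       atp_flux_sum = 4.5 * mu_max,
       nadph_flux_sum = 2.5 * mu_max,
       nadh_flux_sum = 0,
       atp_nadph_ratio = 1.8)
}

#' Chain model with an internal thermodynamically infeasible cycle
#'
#' A linear chain (3 steps, uptake 10) plus a directed internal cycle of
#' `cycle_len` reactions through the chain's second metabolite, detached
#' from all exchanges. FBA may place arbitrary circulation on the cycle
#' (any value is steady-state feasible); loopless correction must zero it
#' without touching the objective or any exchange flux.
#'
#' @param cycle_len Number of reactions in the cycle (>= 3).
#' @return A [metabolic_model()]; cycle reaction ids are `"LOOP1"` ...
#' @export
make_internal_cycle_model <- function(cycle_len = 3L) {
  stopifnot(cycle_len >= 3)
  base <- make_linear_chain(3L, 10)
  cyc_m <- paste0("loopmet", seq_len(cycle_len - 1L), "_c")
  mets <- rbind(base$metabolites,
                do.call(rbind, lapply(cyc_m, function(id)
                  metabolite(id, formula = "C"))))
  ring <- c("m2_c", cyc_m, "m2_c")
  loop_rxns <- lapply(seq_len(cycle_len), function(k)
    reaction(paste0("LOOP", k),
             stats::setNames(c(-1, 1), ring[c(k, k + 1L)]),
             lb = 0, ub = 1000, gene_associated = TRUE,
             subsystem = "internal cycle"))
  rxns <- c(lapply(seq_len(n_reactions(base)), function(k)
    reaction(base$reactions$id[k], base$stoichiometry[[k]],
             lb = base$reactions$lb[k], ub = base$reactions$ub[k],
             name = base$reactions$name[k],
             gene_associated = base$reactions$gene_associated[k])),
    loop_rxns)
  metabolic_model(mets, rxns, objective = c(EX_Z = 1),
                  annotations = list(model_id =
                                       sprintf("cycle_%d", cycle_len)))
}

#' Random feasible network
#'
#' Draws a sparse stoichiometric matrix around a planted non-negative flux
#' vector: the flux vector is sampled first, then each metabolite row is
#' given random coefficients on a random reaction subset with one
#' coefficient solved to put the planted vector in the null space exactly.
#' Bounds enclose the planted vector, so the model is feasible by
#' construction; everything is deterministic per seed.
#'
#' @param n_mets Number of metabolites (>= 2).
#' @param n_rxns Number of reactions (> n_mets).
#' @param seed Integer seed.
#' @return A [metabolic_model()] with the last reaction as objective and
#'   attribute `"planted_flux"`.
#' @export
make_random_feasible <- function(n_mets, n_rxns, seed) {
  if (!(n_rxns > n_mets && n_mets >= 2))
    stop("need n_rxns > n_mets >= 2", call. = FALSE)
  set.seed(seed)
  v <- stats::runif(n_rxns, 0.5, 2)
  met_ids <- paste0("x", seq_len(n_mets), "_c")
  stoich_rows <- matrix(0, n_mets, n_rxns)
  for (i in seq_len(n_mets)) {
    k <- sample(3:min(5, n_rxns), 1)
    js <- sample(n_rxns, k)
    coefs <- stats::runif(k - 1, -2, 2)
    bal <- -sum(coefs * v[js[-k]]) / v[js[k]]
    stoich_rows[i, js] <- c(coefs, bal)
  }
  mets <- do.call(rbind, lapply(met_ids, metabolite))
  rxns <- lapply(seq_len(n_rxns), function(j) {
    st <- stoich_rows[, j]
    names(st) <- met_ids
    st <- st[st != 0]
    reaction(paste0("r", j), st, lb = 0, ub = 2 * v[j] + 1,
             gene_associated = j != n_rxns)
  })
  m <- metabolic_model(mets, rxns,
                       objective = stats::setNames(1, paste0("r", n_rxns)),
                       annotations = list(model_id =
                                            sprintf("rnd_%d_%d_%d", n_mets,
                                                    n_rxns, seed)))
  attr(m, "planted_flux") <- stats::setNames(v, m$reactions$id)
  m
}
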