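# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's simplex path where possible:
# vertex enumeration is pure linear algebra.

# Enumerate all basic feasible solutions (vertices) of
# {v : S v = 0, lb <= v <= ub} and return the best value of cvec'v.
# Exact for small models; independent of the LP solver.
vertex_optimum <- function(model, objective_id, sense = "max") {
  S <- as.matrix(cyanoflux::stoichiometric_matrix(model))
  n <- ncol(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  cvec <- numeric(n)
  cvec[match(objective_id, model$reactions$id)] <- 1
  qr_S <- qr(t(S))          # row space of S
  r <- qr_S$rank
  # independent rows of S
  qr_rows <- qr(S)
  Sind <- S[sort(qr(t(S))$pivot[seq_len(r)]), , drop = FALSE]
  if (r == 0) Sind <- matrix(0, 0, n)
  best <- NA_real_
  tol <- 1e-8
  nb_count <- n - r
  basic_sets <- utils::combn(n, r, simplify = FALSE)
  for (B in basic_sets) {
    SB <- Sind[, B, drop = FALSE]
    if (r > 0 && abs(det(SB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    if (!nrow(grid)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      vN <- ifelse(unlist(grid[g, ]), ub[N], lb[N])
      vN[!is.finite(vN)] <- sign(vN[!is.finite(vN)]) * 1e5
      v <- numeric(n)
      v[N] <- vN
      if (r > 0) {
        rhs <- -Sind[, N, drop = FALSE] %*% vN
        v[B] <- solve(SB, rhs)
      }
      if (any(v < lb - tol | v > ub + tol)) next
      val <- sum(cvec * v)
      if (is.na(best) || (sense == "max" && val > best) ||
          (sense == "min" && val < best)) best <- val
    }
  }
  best
}

# Independent pFBA oracle: explicit split LP built from scratch (every
# penalized reaction replaced by two non-negative direction variables, no
# shared code with cyanoflux::pfba's formulation).
split_pfba_l1 <- function(model, objective_id, zstar) {
  S <- as.matrix(cyanoflux::stoichiometric_matrix(model))
  ids <- model$reactions$id
  n <- ncol(S)
  pen <- which(model$reactions$gene_associated &
                 !vapply(ids, function(id)
                   cyanoflux::is_boundary_reaction(model, id), logical(1)))
  free <- setdiff(seq_len(n), pen)
  # variables: v_free, then (fwd, bwd) per penalized reaction
  nf <- length(free); np <- length(pen)
  Abig <- cbind(S[, free, drop = FALSE],
                S[, pen, drop = FALSE], -S[, pen, drop = FALSE])
  lb <- c(model$reactions$lb[free], pmax(model$reactions$lb[pen], 0),
          pmax(-model$reactions$ub[pen], 0))
  ub <- c(model$reactions$ub[free], pmax(model$reactions$ub[pen], 0),
          pmax(-model$reactions$lb[pen], 0))
  cv <- numeric(nf + 2 * np)
  oj <- match(objective_id, ids)
  if (oj %in% free) cv[match(oj, free)] <- 1
  else {
    k <- match(oj, pen)
    cv[nf + k] <- 1; cv[nf + np + k] <- -1
  }
  # objective held in the same relative band the pFBA contract documents
  slack <- 1e-9 * max(abs(zstar), 1)
  A <- rbind(Abig, cv, cv)
  obj <- c(numeric(nf), rep(1, 2 * np))
  res <- cyanoflux::solve_lp(obj, A,
                             c(rep("=", nrow(Abig)), ">=", "<="),
                             c(rep(0, nrow(Abig)), zstar - slack,
                               zstar + slack),
                             lb, ub, maximize = FALSE)
  stopifnot(res$status == "optimal")
  sum(res$x[nf + seq_len(2 * np)])
}

# Fixture: two routes from a to b, one direct, one via an intermediate.
parallel_routes_model <- function(uptake = 10) {
  mets <- rbind(cyanoflux::metabolite("a_c", formula = "C"),
                cyanoflux::metabolite("i_c", formula = "C"),
                cyanoflux::metabolite("b_c", formula = "C"))
  rxns <- list(
    cyanoflux::reaction("EX_A", c(a_c = -1), lb = -uptake, ub = 1000,
                        gene_associated = FALSE),
    cyanoflux::reaction("DIRECT", c(a_c = -1, b_c = 1)),
    cyanoflux::reaction("VIA1", c(a_c = -1, i_c = 1)),
    cyanoflux::reaction("VIA2", c(i_c = -1, b_c = 1)),
    cyanoflux::reaction("EX_B", c(b_c = -1), lb = 0, ub = 1000,
                        gene_associated = FALSE))
  cyanoflux::metabolic_model(mets, rxns, objective = c(EX_B = 1),
                             annotations = list(model_id = "parallel"))
}

# Fixture: two equivalent single-step routes (alternate optima for FVA).
twin_routes_model <- function(uptake = 10) {
  mets <- rbind(cyanoflux::metabolite("a_c", formula = "C"),
                cyanoflux::metabolite("b_c", formula = "C"))
  rxns <- list(
    cyanoflux::reaction("EX_A", c(a_c = -1), lb = -uptake, ub = 1000,
                        gene_associated = FALSE),
    cyanoflux::reaction("R1", c(a_c = -1, b_c = 1)),
    cyanoflux::reaction("R2", c(a_c = -1, b_c = 1)),
    cyanoflux::reaction("EX_B", c(b_c = -1), lb = 0, ub = 1000,
                        gene_associated = FALSE))
  cyanoflux::metabolic_model(mets, rxns, objective = c(EX_B = 1),
                             annotations = list(model_id = "twin"))
}

# Fixture: minimal base network shaped like the genome-scale model the
# shipped curation config targets (synthetic stand-in carrying exactly the
# species and reaction ids the config edits reference).
mini_base_model <- function() {
  met <- function(id, formula = "") cyanoflux::metabolite(id,
                                                          formula = formula)
  ids <- c("akg_c", "succ_c", "f6p_c", "pi_c", "actp_c", "e4p_c", "h2o_c",
           "xu5p__D_c", "g3p_c", "6pgc_c", "pyr_c", "3pg_c", "nad_c",
           "nadh_c", "h_c", "3php_c", "glu__L_c", "pser__L_c", "ser__L_c",
           "pphn_c", "phpyr_c", "tyr__L_c", "nadp_c", "nadph_c", "q8_c",
           "q8h2_c", "o2_c", "co2_c", "gly_c", "lpro_c", "alpro_c",
           "thf_c", "mlthf_c", "nh4_c", "dhlpro_c", "atp_c", "adp_c",
           "leu__L_c", "4mop_c")
  mets <- do.call(rbind, lapply(ids, met))
  rxns <- list(
    cyanoflux::reaction("NADTRHD", c(nadh_c = -1, nadp_c = -1, nad_c = 1,
                                     nadph_c = 1), lb = 0),
    cyanoflux::reaction("CBFCum", c(q8h2_c = -1, q8_c = 1), lb = 0),
    cyanoflux::reaction("CYO1b2um", c(q8h2_c = -2, o2_c = -1, q8_c = 2,
                                      h2o_c = 2), lb = 0),
    cyanoflux::reaction("NDH1um", c(nadh_c = -1, q8_c = -1, nad_c = 1,
                                    q8h2_c = 1), lb = 0),
    cyanoflux::reaction("LEUTAi", c(akg_c = -1, leu__L_c = -1,
                                    glu__L_c = 1, `4mop_c` = 1), lb = 0),
    cyanoflux::reaction("GLYCL", c(gly_c = -1, thf_c = -1, nad_c = -1,
                                   mlthf_c = 1, nh4_c = 1, co2_c = 1,
                                   nadh_c = 1), lb = 0),
    cyanoflux::reaction("GLYCL_2", c(gly_c = -1, thf_c = -1, nadp_c = -1,
                                     mlthf_c = 1, nh4_c = 1, co2_c = 1,
                                     nadph_c = 1), lb = 0),
    cyanoflux::reaction("EX_o2_e_stub", c(o2_c = -1), lb = -1000,
                        gene_associated = FALSE))
  cyanoflux::metabolic_model(mets, rxns, objective = c(NADTRHD = 1),
                             annotations = list(model_id = "mini_base"))
}

expect_flux_equal <- function(a, b, tol = 1e-6) {
  testthat::expect_lt(max(abs(a - b)), tol)
}

steady_state_residual <- function(model, fs) {
  S <- cyanoflux::stoichiometric_matrix(model)
  max(c(0, abs(as.numeric(S %*% fs$fluxes[colnames(S)]))))
}
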