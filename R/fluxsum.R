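#' Flux-sum (turnover) of a metabolite
#'
#' The flux-sum of metabolite i is half the absolute sum of its
#' stoichiometry-weighted fluxes, `Phi_i = 0.5 * sum_j |S_ij * v_j|`. Under
#' steady state the producing and consuming halves are equal, so `Phi_i`
#' proxies the metabolite's turnover rate. Producers are the reactions with
#' `S_ij * v_j` above a small activity threshold, consumers those below its
#' negative; each active reaction sits on exactly one side.
#'
#' @param model A metabolic model.
#' @param fs An optimal [flux_state()].
#' @param metabolite_id Metabolite id (e.g. `"atp_c"`).
#' @param tol Activity threshold on `S_ij * v_j` (default 1e-9).
#' @return Object of class `"flux_sum_report"`: list with `metabolite_id`,
#'   `phi` (mmol/gDW/h), and data.frames `producers` / `consumers` with
#'   columns `id`, `contribution` (absolute rate), `percent` (share of Phi).
#'   `Phi = 0` yields empty producer/consumer tables.
#' @export
flux_sum <- function(model, fs, metabolite_id, tol = 1e-9) {
  stopifnot(identical(fs$status, "optimal"))
  i <- match(metabolite_id, model$metabolites$id)
  if (is.na(i)) stop(sprintf("unknown metabolite '%s'", metabolite_id),
                     call. = FALSE)
  v <- fs$fluxes[model$reactions$id]
  rates <- vapply(seq_len(n_reactions(model)), function(j) {
    st <- model$stoichiometry[[j]]
    cf <- st[metabolite_id]
    if (is.na(cf)) 0 else cf * v[[j]]
  }, numeric(1))
  phi <- 0.5 * sum(abs(rates))
  side <- function(sel, sign) {
    contrib <- sign * rates[sel]
    ord <- order(contrib, decreasing = TRUE)
    data.frame(id = model$reactions$id[sel][ord],
               contribution = unname(contrib[ord]),
               percent = if (phi > 0) unname(100 * contrib[ord] / phi)
                         else numeric(length(ord)),
               stringsAsFactors = FALSE)
  }
  structure(list(metabolite_id = metabolite_id, phi = phi,
                 producers = side(rates > tol, 1),
                 consumers = side(rates < -tol, -1)),
            class = "flux_sum_report")
}

#' @export
print.flux_sum_report <- function(x, ...) {
  cat(sprintf("flux-sum of %s: Phi = %.4f mmol/gDW/h (%d producers, %d consumers)\n",
              x$metabolite_id, x$phi, nrow(x$producers), nrow(x$consumers)))
  invisible(x)
}

#' Producer/consumer breakdown table for a metabolite
#'
#' Formats a [flux_sum()] report the way the cofactor tables are printed:
#' rows sorted by contribution, fluxes rounded to 2 decimals, and
#' contributions below `display_threshold` displayed as zero while still
#' counted in the percentages (which therefore total 100 per side).
#'
#' @inheritParams flux_sum
#' @param display_threshold Display cut-off in mmol/gDW/h (default 0.01).
#' @return data.frame with columns `side`, `id`, `flux` (signed, rounded;
#'   below-threshold rendered 0), `contribution` (exact), `percent`.
#' @export
producer_consumer_table <- function(model, fs, metabolite_id,
                                    display_threshold = 0.01) {
  rep <- flux_sum(model, fs, metabolite_id)
  one <- function(df, side, sgn) {
    if (!nrow(df)) return(NULL)
    shown <- ifelse(df$contribution < display_threshold, 0,
                    round(sgn * df$contribution, 2))
    data.frame(side = side, id = df$id, flux = shown,
               contribution = df$contribution, percent = df$percent,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(rep$producers, "producer", 1),
               one(rep$consumers, "consumer", -1))
  if (is.null(out))
    out <- data.frame(side = character(0), id = character(0),
                      flux = numeric(0), contribution = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
  structure(out, metabolite_id = metabolite_id, phi = rep$phi,
            class = c("pc_table", "data.frame"))
}

#' Cofactor turnover report
#'
#' Flux-sums of the energy and redox carriers (defaults: cytoplasmic ATP,
#' NADPH, NADH) and the ATP/NADPH ratio. The ratio is `NA` (undefined), not
#' infinite, when the NADPH flux-sum is zero.
#'
#' @param model A metabolic model.
#' @param fs An optimal [flux_state()].
#' @param cofactor_ids Named character vector mapping roles `atp`, `nadph`,
#'   `nadh` to metabolite ids.
#' @return Object of class `"cofactor_report"`: list with `turnover` (named
#'   numeric, mmol/gDW/h) and `atp_nadph_ratio`.
#' @export
cofactor_report <- function(model, fs,
                            cofactor_ids = c(atp = "atp_c",
                                             nadph = "nadph_c",
                                             nadh = "nadh_c")) {
  stopifnot(all(c("atp", "nadph") %in% names(cofactor_ids)))
  missing <- setdiff(unname(cofactor_ids), model$metabolites$id)
  if (length(missing))
    stop("cofactor metabolite(s) not in model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  turn <- vapply(cofactor_ids, function(m) flux_sum(model, fs, m)$phi,
                 numeric(1))
  ratio <- if (turn[["nadph"]] > 0) turn[["atp"]] / turn[["nadph"]]
           else NA_real_
  structure(list(turnover = turn, atp_nadph_ratio = ratio),
            class = "cofactor_report")
}

#' @export
print.cofactor_report <- function(x, ...) {
  cat("cofactor turnover (mmol/gDW/h):\n")
  print(round(x$turnover, 4))
  cat(sprintf("ATP/NADPH ratio: %s\n",
              if (is.na(x$atp_nadph_ratio)) "undefined"
              else sprintf("%.4f", x$atp_nadph_ratio)))
  invisible(x)
}

molar_mass <- function(formula) {
  weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
               S = 32.06, Mg = 24.305, Fe = 55.845, K = 39.098,
               Na = 22.99, Cl = 35.45, Ca = 40.078, Zn = 65.38,
               Cu = 63.546, Mn = 54.938, Mo = 95.95, Co = 58.933)
  cnts <- parse_formula(formula)
  unknown <- setdiff(names(cnts), names(weights))
  if (length(unknown))
    stop("no atomic weight for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sum(cnts * weights[names(cnts)]) / 1000  # g/mmol
}

carbon_count <- function(model, metabolite_id) {
  f <- model$metabolites$formula[match(metabolite_id, model$metabolites$id)]
  if (is.na(f) || !nzchar(f))
    stop("metabolite '", metabolite_id,
         "' has no formula; cannot count carbons", call. = FALSE)
  cnts <- parse_formula(f)
  if ("C" %in% names(cnts)) unname(cnts[["C"]]) else 0
}

#' Productivity, mass yield and c-mol yield
#'
#' Productivity is the product export flux (mmol/gDW/h; for a biomass
#' objective it is the growth rate in 1/h). Mass yield is grams of product
#' per gram of substrate consumed; c-mol yield is moles of product carbon
#' per mole of substrate carbon consumed. Substrate uptakes are the absolute
#' values of negative exchange fluxes over `substrate_exchange_ids`.
#'
#' @param model A metabolic model.
#' @param fs An optimal [flux_state()].
#' @param product_id Metabolite id of the product (used for formula-based
#'   carbon and mass accounting), e.g. `"eth_c"`.
#' @param product_flux_id Reaction id whose flux is the productivity (the
#'   export reaction, or the biomass reaction).
#' @param substrate_exchange_ids Character vector of substrate exchange
#'   reaction ids.
#' @param substrate_id Metabolite id of the substrate (formula source).
#' @param product_mass,substrate_mass g/mmol; computed from formulas when
#'   `NULL`.
#' @return Object of class `"yield_report"`: list with `productivity`,
#'   `mass_yield`, `cmol_yield`, `substrate_uptake` (mmol/gDW/h).
#' @export
yields <- function(model, fs, product_id, product_flux_id,
                   substrate_exchange_ids, substrate_id,
                   product_mass = NULL, substrate_mass = NULL) {
  stopifnot(identical(fs$status, "optimal"))
  v <- fs$fluxes
  prod_flux <- v[[product_flux_id]]
  upt <- vapply(substrate_exchange_ids, function(id) {
    f <- v[[id]]
    if (f < 0) -f else 0
  }, numeric(1))
  total_uptake <- sum(upt)
  if (total_uptake <= 1e-12)
    stop("zero total substrate uptake; yields undefined", call. = FALSE)
  f_prod <- model$metabolites$formula[match(product_id,
                                            model$metabolites$id)]
  if (is.null(product_mass)) product_mass <- molar_mass(f_prod)
  if (is.null(substrate_mass)) {
    f_sub <- model$metabolites$formula[match(substrate_id,
                                             model$metabolites$id)]
    substrate_mass <- molar_mass(f_sub)
  }
  c_prod <- carbon_count(model, product_id)
  c_sub <- carbon_count(model, substrate_id)
  structure(list(
    productivity = prod_flux,
    mass_yield = (prod_flux * product_mass) / (total_uptake * substrate_mass),
    cmol_yield = (prod_flux * c_prod) / (total_uptake * c_sub),
    substrate_uptake = total_uptake), class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat(sprintf("productivity %.4g, mass yield %.4g g/g, c-mol yield %.4g\n",
              x$productivity, x$mass_yield, x$cmol_yield))
  invisible(x)
}
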