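#' Flux state of a model
#'
#' Container for one steady-state flux vector, as returned by [fba()],
#' [pfba()], [remove_loops()] or [two_step_optimize()]. On construction with
#' status `"optimal"` the steady-state residual `max |S v|` and bound
#' feasibility are asserted to the feasibility tolerance.
#'
#' @param model The model the fluxes belong to.
#' @param fluxes Named numeric vector, reaction id to flux (mmol/gDW/h).
#' @param objective_value Objective value Z.
#' @param status One of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @param method One of `"fba"`, `"pfba"`, `"loopless"`, `"two_step"`.
#' @param tol Feasibility tolerance (default 1e-6).
#' @param extra Named list of extra metadata (e.g. `mu_max` for two-step).
#' @return Object of class `"flux_state"`.
#' @export
flux_state <- function(model, fluxes, objective_value, status,
                       method = "fba", tol = 1e-6, extra = list()) {
  if (identical(status, "optimal")) {
    S <- stoichiometric_matrix(model)
    resid <- max(c(0, abs(as.numeric(S %*% fluxes[colnames(S)]))))
    if (resid > tol)
      stop(sprintf("flux state violates steady state: max |S v| = %g", resid),
           call. = FALSE)
    lo <- model$reactions$lb - tol
    hi <- model$reactions$ub + tol
    v <- fluxes[model$reactions$id]
    if (any(v < lo | v > hi))
      stop("flux state violates reaction bounds", call. = FALSE)
  }
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, method = method, extra = extra),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("flux_state (%s): status %s, Z = %.6g, %d reactions\n",
              x$method, x$status, x$objective_value, length(x$fluxes)))
  invisible(x)
}

lp_parts <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  list(S = S,
       sense = rep("=", nrow(S)),
       rhs = rep(0, nrow(S)),
       lb = model$reactions$lb,
       ub = model$reactions$ub,
       ids = model$reactions$id)
}

obj_vector <- function(model, objective_reaction_id = NULL) {
  n <- n_reactions(model)
  cvec <- numeric(n)
  if (is.null(objective_reaction_id)) {
    if (!length(model$objective)) stop("model has no objective", call. = FALSE)
    cvec[match(names(model$objective), model$reactions$id)] <-
      unname(model$objective)
  } else {
    idx <- match(objective_reaction_id, model$reactions$id)
    if (is.na(idx)) stop(sprintf("unknown reaction '%s'",
                                 objective_reaction_id), call. = FALSE)
    cvec[idx] <- 1
  }
  cvec
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject to
#' steady state (`S v = 0`) and flux bounds.
#'
#' @param model A metabolic model.
#' @param objective_reaction_id Reaction to optimize; `NULL` uses the model's
#'   stored objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @param tol Feasibility tolerance for the returned state.
#' @return A [flux_state()].
#' @export
fba <- function(model, objective_reaction_id = NULL, sense = "max",
                tol = 1e-6) {
  p <- lp_parts(model)
  cvec <- obj_vector(model, objective_reaction_id)
  res <- solve_lp(cvec, p$S, p$sense, p$rhs, p$lb, p$ub,
                  maximize = identical(sense, "max"))
  if (res$status != "optimal") {
    fs <- flux_state(model, stats::setNames(rep(NA_real_, length(p$ids)),
                                            p$ids),
                     NA_real_, status = res$status, method = "fba")
    if (res$status == "unbounded")
      fs$extra$unbounded_support <- p$ids[res$unbounded_support]
    return(fs)
  }
  flux_state(model, stats::setNames(res$x, p$ids), res$objval,
             status = "optimal", method = "fba", tol = tol)
}

pfba_penalty_set <- function(model) {
  which(model$reactions$gene_associated &
          !vapply(model$reactions$id, function(id)
            is_boundary_reaction(model, id), logical(1)))
}

#' Parsimonious FBA
#'
#' FBA followed by minimization of the total absolute flux through all
#' gene-associated reactions, with the objective fixed at its FBA optimum.
#' Absolute values are realized by splitting each penalized reaction into two
#' non-negative components. Boundary, biomass and maintenance
#' pseudo-reactions are excluded from the penalty.
#'
#' @inheritParams fba
#' @param fix_tol Relative tolerance for fixing the objective at its optimum.
#' @return A [flux_state()] with method `"pfba"`; `extra$l1_norm` holds the
#'   minimized penalized L1 norm.
#' @export
pfba <- function(model, objective_reaction_id = NULL, tol = 1e-6,
                 fix_tol = 1e-9) {
  first <- fba(model, objective_reaction_id, "max", tol = tol)
  if (first$status != "optimal") return(first)
  zstar <- first$objective_value
  res <- pfba_lp(model, obj_vector(model, objective_reaction_id), zstar,
                 fix_tol)
  if (res$status != "optimal") {
    # numerically too tight objective fixing: retry relaxed, then give up
    res <- pfba_lp(model, obj_vector(model, objective_reaction_id), zstar,
                   1e-6)
    if (res$status != "optimal")
      stop("pFBA infeasible after fixing objective at its optimum",
           call. = FALSE)
  }
  fs <- flux_state(model, res$fluxes, zstar, status = "optimal",
                   method = "pfba", tol = tol)
  fs$extra$l1_norm <- res$l1
  fs
}

pfba_lp <- function(model, cvec, zstar, fix_tol) {
  p <- lp_parts(model)
  n <- length(p$ids)
  pen <- pfba_penalty_set(model)
  m <- length(pen)
  # variables: v (n), pos (m), neg (m)
  A_ss <- cbind(p$S, matrix(0, nrow(p$S), 2 * m))
  A_split <- cbind(matrix(0, m, n), diag(m), -diag(m))
  for (k in seq_along(pen)) A_split[k, pen[k]] <- -1  # -v + p - n = 0
  slack <- max(abs(zstar), 1) * fix_tol
  A_fix <- rbind(c(cvec, numeric(2 * m)), c(cvec, numeric(2 * m)))
  A <- rbind(A_ss, A_split, A_fix)
  sense <- c(p$sense, rep("=", m), ">=", "<=")
  rhs <- c(p$rhs, rep(0, m), zstar - slack, zstar + slack)
  lb <- c(p$lb, rep(0, 2 * m))
  ub <- c(p$ub, rep(Inf, 2 * m))
  objc <- c(numeric(n), rep(1, 2 * m))
  res <- solve_lp(objc, A, sense, rhs, lb, ub, maximize = FALSE)
  if (res$status != "optimal") return(list(status = res$status))
  v <- res$x[seq_len(n)]
  list(status = "optimal", fluxes = stats::setNames(v, p$ids),
       l1 = sum(abs(v[pen])))
}

#' Flux variability analysis
#'
#' For each reaction, minimum and maximum attainable flux subject to the
#' model constraints plus the objective being at least `fraction` of its
#' optimum. With `loopless = TRUE` each subproblem's solution is
#' cycle-corrected with [remove_loops()] before the reaction's flux is read
#' off, so thermodynamically infeasible cycle capacity is not reported.
#'
#' @inheritParams fba
#' @param fraction Fraction of the optimum in (0, 1].
#' @param loopless Logical; cycle-correct each subproblem solution.
#' @param reactions Optional character vector restricting the report.
#' @return Object of class `"fva_result"`: data.frame with columns `id`,
#'   `min`, `max`, plus attribute `fraction`. Per-reaction subproblem
#'   failures are recorded as `NA` rows, not errors.
#' @export
fva <- function(model, objective_reaction_id = NULL, fraction = 0.95,
                loopless = FALSE, reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  first <- fba(model, objective_reaction_id, "max")
  if (first$status != "optimal")
    stop("FVA requires a finite FBA optimum; status: ", first$status,
         call. = FALSE)
  zstar <- first$objective_value
  thresh <- if (zstar >= 0) fraction * zstar else zstar / fraction
  p <- lp_parts(model)
  cvec <- obj_vector(model, objective_reaction_id)
  A <- rbind(p$S, cvec)
  sense <- c(p$sense, ">=")
  rhs <- c(p$rhs, thresh)
  ids <- if (is.null(reactions)) p$ids else reactions
  out <- data.frame(id = ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    j <- match(ids[k], p$ids)
    ej <- numeric(length(p$ids)); ej[j] <- 1
    for (dir in c("min", "max")) {
      res <- solve_lp(ej, A, sense, rhs, p$lb, p$ub,
                      maximize = identical(dir, "max"))
      if (res$status %in% c("optimal", "unbounded")) {
        val <- res$x[j]
        if (loopless && res$status == "optimal") {
          fs <- flux_state(model, stats::setNames(res$x, p$ids),
                           sum(cvec * res$x), "optimal", method = "fba")
          val <- remove_loops(model, fs)$fluxes[[ids[k]]]
        }
        out[[dir]][k] <- val
      }
    }
  }
  structure(out, fraction = fraction, class = c("fva_result", "data.frame"))
}

internal_reactions <- function(model) {
  !vapply(model$reactions$id, function(id) is_boundary_reaction(model, id),
          logical(1))
}

#' Detect a thermodynamically infeasible cycle in a flux state
#'
#' A flux vector carries a loop if a nonzero internal circulation exists that
#' is sign-compatible with it: `S w = 0`, `w = 0` on boundary reactions and
#' on inactive reactions, and `w_j` sharing the sign of `v_j` elsewhere.
#' Checked by maximizing the circulation's total flux by LP.
#'
#' @param model A metabolic model.
#' @param fs A [flux_state()].
#' @param tol Activity threshold.
#' @return Logical.
#' @export
has_loop <- function(model, fs, tol = 1e-6) {
  v <- fs$fluxes[model$reactions$id]
  intr <- internal_reactions(model)
  n <- length(v)
  lb <- numeric(n); ub <- numeric(n)
  act_pos <- intr & v > tol
  act_neg <- intr & v < -tol
  ub[act_pos] <- 1
  lb[act_neg] <- -1
  if (!any(act_pos | act_neg)) return(FALSE)
  p <- lp_parts(model)
  objc <- numeric(n); objc[act_pos] <- 1; objc[act_neg] <- -1
  res <- solve_lp(objc, p$S, p$sense, p$rhs, lb, ub, maximize = TRUE)
  res$status == "optimal" && res$objval > tol * 10
}

#' Remove thermodynamically infeasible cycles from a flux state
#'
#' Post-hoc cycle correction in the CycleFreeFlux style: with every boundary
#' flux fixed at its current value, minimize the total absolute flux through
#' internal reactions, constraining each internal flux to keep its sign and
#' not exceed its current magnitude. The result carries identical exchange
#' fluxes and objective value and no internal cycle flux, without integer
#' programming. `strict = TRUE` instead solves the exact loop-law problem by
#' exhaustive direction-pattern enumeration; it is only available on small
#' instances (<= `strict_cap` loopable reactions) and errors otherwise.
#'
#' @param model A metabolic model.
#' @param fs An optimal [flux_state()].
#' @param strict Use the exact enumeration formulation.
#' @param strict_cap Maximum number of loopable reactions for strict mode.
#' @param tol Numeric tolerance.
#' @return A [flux_state()] with method `"loopless"`.
#' @export
remove_loops <- function(model, fs, strict = FALSE, strict_cap = 10L,
                         tol = 1e-6) {
  stopifnot(identical(fs$status, "optimal"))
  if (strict) return(remove_loops_strict(model, fs, strict_cap, tol))
  v <- fs$fluxes[model$reactions$id]
  intr <- internal_reactions(model)
  n <- length(v)
  lb <- v; ub <- v      # boundary + inactive fluxes fixed
  pos <- intr & v > tol
  neg <- intr & v < -tol
  lb[pos] <- 0; ub[pos] <- v[pos]
  ub[neg] <- 0; lb[neg] <- v[neg]
  p <- lp_parts(model)
  # minimize sum of |v_j| over internal = sum(v[pos]) - sum(v[neg])
  objc <- numeric(n); objc[pos] <- 1; objc[neg] <- -1
  res <- solve_lp(objc, p$S, p$sense, p$rhs, lb, ub, maximize = FALSE)
  if (res$status != "optimal")
    stop("cycle correction LP failed: ", res$status, call. = FALSE)
  out <- stats::setNames(res$x, p$ids)
  flux_state(model, out, fs$objective_value, "optimal",
             method = "loopless", tol = max(tol, 1e-6),
             extra = c(fs$extra, list(corrected_from = fs$method)))
}

loopable_reactions <- function(model) {
  # internal reactions that can carry flux with all boundary fluxes at zero
  p <- lp_parts(model)
  intr <- internal_reactions(model)
  n <- length(p$ids)
  lb <- ifelse(intr, pmax(p$lb, -1), 0)
  ub <- ifelse(intr, pmin(p$ub, 1), 0)
  out <- logical(n)
  for (j in which(intr)) {
    ej <- numeric(n); ej[j] <- 1
    hi <- solve_lp(ej, p$S, p$sense, p$rhs, lb, ub, maximize = TRUE)
    lo <- solve_lp(ej, p$S, p$sense, p$rhs, lb, ub, maximize = FALSE)
    out[j] <- (hi$status == "optimal" && hi$objval > 1e-7) ||
      (lo$status == "optimal" && lo$objval < -1e-7)
  }
  out
}

remove_loops_strict <- function(model, fs, cap, tol) {
  loopable <- which(loopable_reactions(model))
  if (length(loopable) > cap)
    stop(sprintf(paste0("strict loopless mode needs exhaustive enumeration ",
                        "over %d loopable reactions (cap %d); use the ",
                        "default LP correction instead"),
                 length(loopable), cap), call. = FALSE)
  if (length(loopable) == 0L) {
    out <- fs; out$method <- "loopless"; return(out)
  }
  v <- fs$fluxes[model$reactions$id]
  exch <- !internal_reactions(model)
  p <- lp_parts(model)
  n <- length(p$ids)
  best <- NULL
  patterns <- expand.grid(rep(list(c(-1, 1)), length(loopable)))
  for (r in seq_len(nrow(patterns))) {
    sig <- as.numeric(patterns[r, ])
    lb <- p$lb; ub <- p$ub
    lb[exch] <- v[exch]; ub[exch] <- v[exch]   # keep exchanges
    for (k in seq_along(loopable)) {
      j <- loopable[k]
      if (sig[k] > 0) lb[j] <- max(lb[j], 0) else ub[j] <- min(ub[j], 0)
    }
    objc <- numeric(n)
    pen <- loopable
    # minimize total absolute loopable flux at fixed exchanges
    objc[pen] <- sig
    res <- solve_lp(objc, p$S, p$sense, p$rhs, lb, ub, maximize = FALSE)
    if (res$status != "optimal") next
    cand <- stats::setNames(res$x, p$ids)
    cfs <- flux_state(model, cand, fs$objective_value, "optimal",
                      method = "loopless", tol = 1e-5)
    if (has_loop(model, cfs, tol)) next
    total <- sum(abs(cand[loopable]))
    if (is.null(best) || total < best$total)
      best <- list(fs = cfs, total = total)
  }
  if (is.null(best))
    stop("strict loopless enumeration found no loop-free completion",
         call. = FALSE)
  best$fs
}

#' Two-step biomass-coupled production optimization
#'
#' Step 1 maximizes the biomass reaction (giving `mu_max`); step 2 sets the
#' biomass lower bound to `biomass_fraction * mu_max` and maximizes the
#' production target with parsimonious FBA. This emulates a producing cell
#' that still sustains minimal growth.
#'
#' @param model A metabolic model.
#' @param biomass_id Biomass reaction id.
#' @param target_id Production (export) reaction id.
#' @param biomass_fraction Fraction of maximal growth to enforce (default
#'   0.10).
#' @param parsimonious Use pFBA in step 2 (default); otherwise plain FBA.
#' @return A [flux_state()] with method `"two_step"`; `extra$mu_max` and
#'   `extra$biomass_flux` record the growth ceiling and achieved growth.
#' @export
two_step_optimize <- function(model, biomass_id, target_id,
                              biomass_fraction = 0.10, parsimonious = TRUE) {
  stopifnot(biomass_fraction >= 0, biomass_fraction <= 1)
  growth <- fba(model, biomass_id, "max")
  if (growth$status != "optimal" || growth$objective_value <= 1e-9)
    stop("growth infeasible under scenario (mu_max = 0)", call. = FALSE)
  mu_max <- growth$objective_value
  m2 <- set_bounds(model, biomass_id, lb = biomass_fraction * mu_max)
  m2 <- set_objective(m2, target_id)
  fs <- if (parsimonious) pfba(m2, target_id) else fba(m2, target_id)
  if (fs$status != "optimal")
    stop("production step infeasible at biomass fraction ",
         biomass_fraction, call. = FALSE)
  out <- flux_state(model, fs$fluxes, fs$objective_value, "optimal",
                    method = "two_step", tol = 1e-6,
                    extra = list(mu_max = mu_max,
                                 biomass_fraction = biomass_fraction,
                                 biomass_flux = fs$fluxes[[biomass_id]],
                                 l1_norm = fs$extra$l1_norm))
  out
}

#' Phenotypic phase plane
#'
#' Grid scan of the trade-off between two fluxes: for each of `n_points`
#' values of `rxn_x` fixed between 0 and its maximal attainable rate, the
#' maximal attainable `rxn_y` is computed, and vice versa when
#' `both_axes = TRUE`. Infeasible grid points are flagged, never dropped.
#'
#' @param model A metabolic model.
#' @param rxn_x,rxn_y Reaction ids (e.g. biomass and product export).
#' @param n_points Grid resolution per axis (>= 2, default 50, inclusive
#'   endpoints).
#' @param both_axes Also scan with the roles swapped.
#' @return Object of class `"phase_plane"`: data.frame with columns `axis`
#'   (`"x"` or `"y"`: which reaction was fixed), `fixed_flux`, `max_other`,
#'   `feasible`.
#' @export
phenotypic_phase_plane <- function(model, rxn_x, rxn_y, n_points = 50L,
                                   both_axes = FALSE) {
  stopifnot(n_points >= 2)
  scan_one <- function(fix_id, free_id, axis) {
    top <- fba(model, fix_id, "max")
    if (top$status != "optimal")
      stop("cannot establish maximal rate for ", fix_id, call. = FALSE)
    grid <- seq(0, top$objective_value, length.out = n_points)
    res <- lapply(grid, function(g) {
      m <- set_bounds(model, fix_id, lb = g, ub = g)
      r <- fba(m, free_id, "max")
      data.frame(axis = axis, fixed_flux = g,
                 max_other = if (r$status == "optimal")
                   r$objective_value else NA_real_,
                 feasible = r$status == "optimal",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- scan_one(rxn_x, rxn_y, "x")
  if (both_axes) out <- rbind(out, scan_one(rxn_y, rxn_x, "y"))
  structure(out, rxn_x = rxn_x, rxn_y = rxn_y,
            class = c("phase_plane", "data.frame"))
}
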