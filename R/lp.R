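# Dense two-phase tableau simplex. Written in-package because the flux LPs
# here are small (tens of variables) and the method must be deterministic:
# Dantzig pricing with a Bland anti-cycling fallback, fixed tolerances, no
# threading, so repeated runs agree bit-for-bit at reporting precision.

# One simplex run on a canonical tableau.
# Tb: m x (ncols+1), last column rhs; basis: length-m column indices;
# cost: length-ncols objective (minimization).
simplex_iterate <- function(Tb, basis, cost, tol) {
  m <- nrow(Tb)
  ncols <- ncol(Tb) - 1L
  it <- 0L
  bland_after <- 50L * (m + ncols)
  max_it <- 200L * (m + ncols) + 5000L
  repeat {
    it <- it + 1L
    if (it > max_it) return(list(status = "maxiter", Tb = Tb, basis = basis))
    red <- cost - as.numeric(cost[basis] %*% Tb[, seq_len(ncols),
                                                drop = FALSE])
    red[basis] <- 0
    cand <- which(red < -tol)
    if (!length(cand)) return(list(status = "optimal", Tb = Tb,
                                   basis = basis))
    enter <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])]
    col <- Tb[, enter]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", Tb = Tb,
                                  basis = basis, ray = enter))
    ratios <- Tb[pos, ncols + 1L] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    leave <- if (it > bland_after) ties[which.min(basis[ties])]
             else ties[which.max(col[ties])]
    piv <- Tb[leave, enter]
    Tb[leave, ] <- Tb[leave, ] / piv
    upd <- which(abs(Tb[, enter]) > 0)
    upd <- upd[upd != leave]
    if (length(upd))
      Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, enter], Tb[leave, ])
    basis[leave] <- enter
  }
}

# min obj' x  s.t.  A x = b (b >= 0 after sign fix), x >= 0.
simplex_core <- function(obj, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n)
  b <- pmax(b, 0)

  # phase 1: artificial variables form the starting basis
  Tb <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  r1 <- simplex_iterate(Tb, basis, cost1, tol)
  if (r1$status != "optimal") return(list(status = "infeasible", x = NULL))
  Tb <- r1$Tb; basis <- r1$basis
  infeas <- sum(Tb[basis > n, n + m + 1L])
  if (infeas > 1e-7 * (1 + sum(b)))
    return(list(status = "infeasible", x = NULL))
  # pivot residual zero-valued artificials out; drop redundant rows
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      j <- which(abs(Tb[i, seq_len(n)]) > tol * 100)
      if (length(j)) {
        enter <- j[1L]
        Tb[i, ] <- Tb[i, ] / Tb[i, enter]
        upd <- which(abs(Tb[, enter]) > 0)
        upd <- upd[upd != i]
        if (length(upd))
          Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, enter], Tb[i, ])
        basis[i] <- enter
      } else drop_rows <- c(drop_rows, i)
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
    m <- nrow(Tb)
  }

  # phase 2 on the original columns
  Tb2 <- cbind(Tb[, seq_len(n), drop = FALSE], Tb[, ncol(Tb)],
               deparse.level = 0)
  r2 <- simplex_iterate(Tb2, basis, obj, tol)
  if (r2$status != "optimal") return(list(status = r2$status, x = NULL))
  x <- numeric(n)
  x[r2$basis] <- r2$Tb[, n + 1L]
  x <- pmax(x, 0)
  list(status = "optimal", x = x, objval = sum(obj * x))
}

#' Solve a linear program
#'
#' Minimal LP backend interface used by all optimization routines: optimize
#' `obj' x` subject to `A x (<=, >=, =) rhs` and `lb <= x <= ub`, via the
#' package's deterministic two-phase simplex (single thread, fixed pivoting
#' rules), so degenerate flux LPs resolve identically across runs.
#'
#' Infinite bounds are clamped to `big` internally; a solution pinning an
#' objective-carrying variable at a clamped infinite bound is reported as
#' `"unbounded"` together with the support of the offending variables.
#'
#' @param obj Numeric objective coefficients, length n.
#' @param A Constraint matrix (dense or sparse), possibly 0-row.
#' @param sense Character vector per row of `A`: `"="`, `"<="` or `">="`.
#' @param rhs Right-hand sides per row.
#' @param lb,ub Variable bounds (may contain `-Inf`/`Inf`).
#' @param maximize Logical.
#' @param big Finite stand-in for infinite bounds (default 1e5).
#' @param eps Simplex numerical tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (solution in original variables, or `NULL`),
#'   `objval`, and `unbounded_support` (indices of clamped variables, when
#'   relevant).
#' @export
solve_lp <- function(obj, A, sense, rhs, lb, ub, maximize = TRUE,
                     big = 1e5, eps = 1e-9) {
  n <- length(obj)
  A <- as.matrix(A)
  if (nrow(A) > 0 && ncol(A) != n) stop("A has wrong number of columns")
  stopifnot(length(lb) == n, length(ub) == n, length(sense) == nrow(A),
            length(rhs) == nrow(A))
  clamped_lo <- !is.finite(lb)
  clamped_hi <- !is.finite(ub)
  lb2 <- ifelse(clamped_lo, -big, lb)
  ub2 <- ifelse(clamped_hi, big, ub)
  if (any(lb2 > ub2)) return(list(status = "infeasible", x = NULL,
                                  objval = NA_real_))
  # shift x = v - lb2 so x >= 0; upper bounds become rows x_i <= width_i
  width <- ub2 - lb2
  nrows <- nrow(A)
  rhs2 <- rhs - if (nrows > 0) as.numeric(A %*% lb2) else numeric(0)

  Afull <- rbind(if (nrows > 0) A else NULL, diag(n))
  senses <- c(sense, rep("<=", n))
  bfull <- c(rhs2, width)
  ineq <- which(senses != "=")
  nslack <- length(ineq)
  Aeq <- cbind(Afull, matrix(0, nrow(Afull), nslack))
  for (k in seq_along(ineq)) {
    Aeq[ineq[k], n + k] <- if (senses[ineq[k]] == "<=") 1 else -1
  }
  beq <- bfull
  neg <- which(beq < 0)
  if (length(neg)) {
    Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
    beq[neg] <- -beq[neg]
  }
  shifted_obj <- c(if (maximize) -obj else obj, rep(0, nslack))
  res <- simplex_core(shifted_obj, Aeq, beq, tol = eps)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objval = NA_real_))
  x <- pmin(res$x[seq_len(n)], width) + lb2
  objval <- sum(obj * x)
  at_clamp <- (clamped_hi & x > ub2 - 1e-6 * big) |
    (clamped_lo & x < lb2 + 1e-6 * big)
  if (any(at_clamp & obj != 0)) {
    return(list(status = "unbounded", x = x, objval = objval,
                unbounded_support = which(at_clamp & obj != 0)))
  }
  list(status = "optimal", x = x, objval = objval)
}
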