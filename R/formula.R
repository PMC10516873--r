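#' Parse an elemental formula string
#'
#' Parses a Hill-style elemental formula (e.g. `"C6H12O6"`) into a named
#' integer vector of element counts. Element symbols are one upper-case letter
#' optionally followed by one lower-case letter, each followed by an optional
#' positive integer count (default 1). The empty string is a valid formula and
#' yields an empty count map; metabolites with unknown composition carry it.
#'
#' @param formula A single character string, possibly empty.
#' @return Named numeric vector mapping element symbol to count. Repeated
#'   symbols are summed.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C5H8")
#' parse_formula("")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (nchar(formula) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  pos <- 1L
  n <- nchar(formula)
  counts <- list()
  while (pos <= n) {
    rest <- substr(formula, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || nchar(m[2]) == 0L) {
      stop(sprintf("malformed formula '%s': unexpected token at position %d",
                   formula, pos), call. = FALSE)
    }
    elem <- m[2]
    cnt <- if (nchar(m[3]) == 0L) 1 else as.numeric(m[3])
    if (cnt <= 0) {
      stop(sprintf("malformed formula '%s': non-positive count at position %d",
                   formula, pos), call. = FALSE)
    }
    counts[[length(counts) + 1L]] <- stats::setNames(cnt, elem)
    pos <- pos + nchar(m[1])
  }
  v <- unlist(counts)
  tapply(v, names(v), sum)[unique(names(v))]
}

#' Check elemental mass balance of a reaction
#'
#' Sums stoichiometry-weighted element counts over all participants. An
#' all-zero map means the reaction is elementally balanced. Boundary and
#' declared pseudo-reactions (exchanges, biomass, maintenance) are skipped,
#' as is any reaction touching a metabolite with an empty formula, since the
#' balance is then unverifiable.
#'
#' @param reaction_id Reaction identifier present in `model`.
#' @param model A [metabolic_model()].
#' @return A list with elements `status` (one of `"balanced"`, `"imbalanced"`,
#'   `"boundary"`, `"unverifiable"`) and `imbalance` (named numeric vector of
#'   per-element net counts; empty for skipped reactions).
#' @export
check_mass_balance <- function(reaction_id, model) {
  stopifnot(inherits(model, "metabolic_model"))
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) stop(sprintf("unknown reaction '%s'", reaction_id), call. = FALSE)
  if (is_boundary_reaction(model, reaction_id)) {
    return(list(status = "boundary", imbalance = numeric(0)))
  }
  stoich <- model$stoichiometry[[idx]]
  formulas <- model$metabolites$formula[match(names(stoich), model$metabolites$id)]
  if (any(is.na(formulas)) || any(!nzchar(formulas))) {
    return(list(status = "unverifiable", imbalance = numeric(0)))
  }
  total <- numeric(0)
  for (k in seq_along(stoich)) {
    cnts <- parse_formula(formulas[k]) * stoich[k]
    for (el in names(cnts)) {
      total[el] <- (if (el %in% names(total)) total[[el]] else 0) + cnts[[el]]
    }
  }
  status <- if (all(abs(total) <= 1e-9)) "balanced" else "imbalanced"
  list(status = status, imbalance = total)
}
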