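#' Construct a metabolite table row
#'
#' Helper building one metabolite record for [metabolic_model()].
#'
#' @param id BiGG-style identifier with compartment suffix (e.g. `"atp_c"`).
#' @param name Free-text name.
#' @param compartment Compartment token (defaults to the id suffix after the
#'   last underscore, or `"c"`).
#' @param formula Elemental formula string; may be empty when unknown.
#' @param charge Integer charge.
#' @return A one-row data.frame.
#' @export
metabolite <- function(id, name = id, compartment = NULL, formula = "",
                       charge = 0L) {
  if (is.null(compartment)) {
    compartment <- sub("^.*_([a-z0-9]+)$", "\\1", id)
    if (identical(compartment, id)) compartment <- "c"
  }
  parse_formula(formula)  # validates
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Construct a reaction record
#'
#' @param id BiGG-style reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed). May be empty only for declared
#'   boundary/pseudo reactions.
#' @param lb,ub Flux bounds in mmol/gDW/h; use `-Inf`/`Inf` for unbounded.
#' @param name Free-text name.
#' @param gene_associated Logical; whether any gene product is associated.
#'   Parsimonious FBA minimizes total absolute flux over exactly these.
#' @param subsystem Free-text subsystem.
#' @return A list of class `"cf_reaction"`.
#' @export
reaction <- function(id, stoichiometry, lb = 0, ub = 1000, name = id,
                     gene_associated = TRUE, subsystem = "") {
  stopifnot(is.numeric(stoichiometry))
  if (length(stoichiometry) > 0 && is.null(names(stoichiometry)))
    stop("stoichiometry must be a named numeric vector", call. = FALSE)
  if (lb > ub)
    stop(sprintf("reaction '%s': lower bound %g exceeds upper bound %g",
                 id, lb, ub), call. = FALSE)
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry[stoichiometry != 0],
                 lb = lb, ub = ub,
                 gene_associated = isTRUE(gene_associated),
                 subsystem = subsystem),
            class = "cf_reaction")
}

#' Assemble a metabolic model
#'
#' The central container: a metabolite table, a reaction table with parallel
#' stoichiometry list, objective coefficients (the vector `c` of the FBA
#' objective `max Z = c'v`), and free-form annotations (model id, biomass
#' reaction ids per trophic mode). The steady-state constraint is
#' `S v = 0` with `S` the (n_metabolites x n_reactions) stoichiometric matrix
#' and bound constraints `lb <= v <= ub` per reaction.
#'
#' @param metabolites data.frame as produced by rbinding [metabolite()] rows.
#' @param reactions List of [reaction()] objects.
#' @param objective Named numeric vector, reaction id to objective
#'   coefficient. Reactions absent from it have coefficient 0.
#' @param annotations Named list; `model_id` and optionally `biomass_ids`.
#' @return Object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = numeric(0),
                            annotations = list(model_id = "model")) {
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids", call. = FALSE)
  model <- structure(list(
    metabolites = metabolites,
    reactions = data.frame(
      id = rxn_ids,
      name = vapply(reactions, function(r) r$name, character(1)),
      lb = vapply(reactions, function(r) r$lb, numeric(1)),
      ub = vapply(reactions, function(r) r$ub, numeric(1)),
      gene_associated = vapply(reactions, function(r) r$gene_associated,
                               logical(1)),
      subsystem = vapply(reactions, function(r) r$subsystem, character(1)),
      stringsAsFactors = FALSE),
    stoichiometry = lapply(reactions, function(r) r$stoichiometry),
    objective = objective,
    annotations = annotations), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate internal consistency of a metabolic model
#'
#' Checks that every stoichiometry key resolves to a metabolite, bounds are
#' ordered, and objective ids exist. Called by constructors and after edits.
#'
#' @param model A metabolic model.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- model$metabolites$id
  for (i in seq_along(model$stoichiometry)) {
    missing <- setdiff(names(model$stoichiometry[[i]]), met_ids)
    if (length(missing))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   model$reactions$id[i], paste(missing, collapse = ", ")),
           call. = FALSE)
  }
  if (any(model$reactions$lb > model$reactions$ub))
    stop("some reactions have lb > ub", call. = FALSE)
  bad <- setdiff(names(model$objective), model$reactions$id)
  if (length(bad))
    stop("objective references unknown reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(model)
}

#' Number of reactions / metabolites
#' @param model A metabolic model.
#' @return Integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' Is a reaction a boundary/pseudo reaction?
#'
#' Boundary reactions (exchanges, sinks, demands), biomass drains and the
#' ATP-maintenance pseudo-reaction are not part of the gene-encoded network:
#' exchanges move a single species across the system boundary. Detection:
#' stoichiometry with at most one metabolite, an id prefixed `EX_`, `DM_`,
#' `SK_`, or an id containing `BIOMASS`/`ATPM`.
#'
#' @param model A metabolic model.
#' @param reaction_id Reaction id.
#' @return Logical.
#' @export
is_boundary_reaction <- function(model, reaction_id) {
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) stop(sprintf("unknown reaction '%s'", reaction_id),
                       call. = FALSE)
  id <- model$reactions$id[idx]
  length(model$stoichiometry[[idx]]) <= 1L ||
    grepl("^(EX|DM|SK)_", id) || grepl("BIOMASS|ATPM", id)
}

#' Stoichiometric matrix of a model
#'
#' Builds the sparse matrix `S` with `S[i, j]` the coefficient of metabolite
#' `i` in reaction `j`; row order follows the metabolite table, column order
#' the reaction table.
#'
#' @param model A metabolic model.
#' @return A `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$stoichiometry)) {
    st <- model$stoichiometry[[j]]
    if (!length(st)) next
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Replace the objective of a model
#'
#' Clears all objective coefficients and sets coefficient 1 (or as given) on
#' the named reaction(s).
#'
#' @param model A metabolic model.
#' @param objective Either a reaction id (coefficient 1) or a named numeric
#'   vector of coefficients.
#' @return The modified model.
#' @export
set_objective <- function(model, objective) {
  if (is.character(objective)) objective <- stats::setNames(1, objective)
  bad <- setdiff(names(objective), model$reactions$id)
  if (length(bad))
    stop("objective references unknown reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  model$objective <- objective
  model
}

#' Set bounds of one reaction
#' @param model A metabolic model.
#' @param reaction_id Reaction id.
#' @param lb,ub New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  idx <- match(reaction_id, model$reactions$id)
  if (is.na(idx)) stop(sprintf("unknown reaction '%s'", reaction_id),
                       call. = FALSE)
  if (!is.null(lb)) model$reactions$lb[idx] <- lb
  if (!is.null(ub)) model$reactions$ub[idx] <- ub
  if (model$reactions$lb[idx] > model$reactions$ub[idx])
    stop(sprintf("reaction '%s': lb > ub after update", reaction_id),
         call. = FALSE)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions\n",
              x$annotations$model_id %||% "?", n_metabolites(x),
              n_reactions(x)))
  if (length(x$objective))
    cat("objective:", paste(sprintf("%g*%s", unname(x$objective),
                                    names(x$objective)), collapse = " + "),
        "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic content hash of a model
#'
#' Hash over ids, stoichiometry, bounds, gene flags and objective, used in
#' run manifests so results can be traced to the exact model.
#'
#' @param model A metabolic model.
#' @return A hex string.
#' @export
model_hash <- function(model) {
  s <- paste(
    paste(model$metabolites$id, model$metabolites$formula,
          model$metabolites$charge, collapse = "|"),
    paste(model$reactions$id, model$reactions$lb, model$reactions$ub,
          model$reactions$gene_associated, collapse = "|"),
    paste(vapply(model$stoichiometry, function(s) {
      s <- s[order(names(s))]
      paste(names(s), format(s, digits = 15), sep = ":", collapse = ";")
    }, character(1)), collapse = "|"),
    paste(sort(names(model$objective)),
          model$objective[sort(names(model$objective))], collapse = "|"),
    sep = "||")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}
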