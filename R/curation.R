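#' Declarative model edit set
#'
#' An ordered set of edits to apply to a model: reaction additions, bound
#' changes (applied in listed order, so an id may appear more than once and
#' the last change wins), and removals.
#'
#' @param additions List of [reaction()] objects.
#' @param bound_changes data.frame with columns `id`, `lb`, `ub` (or a list
#'   of such rows).
#' @param removals Character vector of reaction ids.
#' @return Object of class `"edit_set"`.
#' @export
edit_set <- function(additions = list(), bound_changes = NULL,
                     removals = character(0)) {
  if (is.list(bound_changes) && !is.data.frame(bound_changes))
    bound_changes <- do.call(rbind, lapply(bound_changes, function(b)
      data.frame(id = b$id, lb = as.numeric(b$lb), ub = as.numeric(b$ub),
                 stringsAsFactors = FALSE)))
  if (is.null(bound_changes))
    bound_changes <- data.frame(id = character(0), lb = numeric(0),
                                ub = numeric(0), stringsAsFactors = FALSE)
  structure(list(additions = additions, bound_changes = bound_changes,
                 removals = removals), class = "edit_set")
}

#' Apply an edit set to a model
#'
#' Pure function: returns a new model with additions appended, bounds
#' replaced in order, and removals dropped; the input model is unmodified.
#' Additions are mass-checked where metabolite formulas permit; elemental
#' imbalances outside boundary/pseudo reactions are reported as warnings in
#' the attached curation report.
#'
#' @param model A metabolic model.
#' @param edits An [edit_set()].
#' @param new_metabolites Optional data.frame of metabolites the additions
#'   introduce (same shape as `model$metabolites`).
#' @return The edited model, with attribute `"curation_report"` (data.frame
#'   of applied edits and mass-check outcomes).
#' @export
apply_edit_set <- function(model, edits, new_metabolites = NULL) {
  stopifnot(inherits(model, "metabolic_model"), inherits(edits, "edit_set"))
  add_ids <- vapply(edits$additions, function(r) r$id, character(1))
  collide <- intersect(add_ids, model$reactions$id)
  if (length(collide))
    stop("addition id(s) collide with existing reactions: ",
         paste(collide, collapse = ", "), call. = FALSE)
  dangling <- setdiff(c(edits$bound_changes$id, edits$removals),
                      c(model$reactions$id, add_ids))
  if (length(dangling))
    stop("edit references unknown reaction(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)

  out <- model
  if (!is.null(new_metabolites) && nrow(new_metabolites))
    out$metabolites <- rbind(out$metabolites,
                             new_metabolites[!new_metabolites$id %in%
                                               out$metabolites$id, ])
  report <- list()
  for (r in edits$additions) {
    out$reactions <- rbind(out$reactions, data.frame(
      id = r$id, name = r$name, lb = r$lb, ub = r$ub,
      gene_associated = r$gene_associated, subsystem = r$subsystem,
      stringsAsFactors = FALSE))
    out$stoichiometry <- c(out$stoichiometry, list(r$stoichiometry))
    validate_model(out)
    mb <- check_mass_balance(r$id, out)
    report[[length(report) + 1L]] <- data.frame(
      edit = "addition", id = r$id, detail = mb$status,
      stringsAsFactors = FALSE)
  }
  if (nrow(edits$bound_changes)) {
    for (k in seq_len(nrow(edits$bound_changes))) {
      bc <- edits$bound_changes[k, ]
      out <- set_bounds(out, bc$id, lb = bc$lb, ub = bc$ub)
      report[[length(report) + 1L]] <- data.frame(
        edit = "bound_change", id = bc$id,
        detail = sprintf("[%g, %g]", bc$lb, bc$ub), stringsAsFactors = FALSE)
    }
  }
  if (length(edits$removals)) {
    keep <- !out$reactions$id %in% edits$removals
    out$reactions <- out$reactions[keep, , drop = FALSE]
    rownames(out$reactions) <- NULL
    out$stoichiometry <- out$stoichiometry[keep]
    out$objective <- out$objective[!names(out$objective) %in% edits$removals]
    for (id in edits$removals)
      report[[length(report) + 1L]] <- data.frame(
        edit = "removal", id = id, detail = "", stringsAsFactors = FALSE)
  }
  validate_model(out)
  attr(out, "curation_report") <- do.call(rbind, report)
  out
}

#' Add the ATP maintenance pseudo-reaction
#'
#' Appends `ATPM: atp + h2o -> adp + pi + h` (cytoplasmic species), the
#' non-growth-associated maintenance drain. Lower bound is the maintenance
#' flux floor (default 0: no numeric maintenance coefficient is imposed and
#' any maintenance flux emerges from optimization); upper bound is
#' unbounded. Not gene-associated.
#'
#' @param model A metabolic model.
#' @param flux_floor Maintenance floor in mmol/gDW/h.
#' @param compartment Compartment suffix for the species (default `"c"`).
#' @return The model with ATPM added.
#' @export
add_atpm <- function(model, flux_floor = 0, compartment = "c") {
  sp <- paste0(c("atp", "h2o", "adp", "pi", "h"), "_", compartment)
  missing <- setdiff(sp, model$metabolites$id)
  if (length(missing))
    stop("cannot add ATPM; missing species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if ("ATPM" %in% model$reactions$id)
    stop("addition id(s) collide with existing reactions: ATPM",
         call. = FALSE)
  st <- stats::setNames(c(-1, -1, 1, 1, 1), sp)
  apply_edit_set(model, edit_set(additions = list(
    reaction("ATPM", st, lb = flux_floor, ub = Inf,
             name = "ATP maintenance requirement",
             gene_associated = FALSE, subsystem = "Maintenance"))))
}

#' Heterologous pathway definition
#'
#' A named set of reactions plus the id of the product export
#' pseudo-reaction, to be grafted onto a curated model with [add_pathway()].
#'
#' @param name Pathway name (e.g. `"isoprene"`).
#' @param reactions List of [reaction()] objects (the export reaction
#'   included).
#' @param export_reaction_id Id of the export pseudo-reaction; must consume
#'   exactly one cytoplasmic species.
#' @param new_metabolites Optional metabolite data.frame for intermediates
#'   the pathway introduces.
#' @return Object of class `"pathway_definition"`.
#' @export
pathway_definition <- function(name, reactions, export_reaction_id,
                               new_metabolites = NULL) {
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (!export_reaction_id %in% ids)
    stop("export_reaction_id not among pathway reactions", call. = FALSE)
  exp_st <- reactions[[match(export_reaction_id, ids)]]$stoichiometry
  if (!(length(exp_st) == 1L && exp_st < 0))
    stop("export reaction must consume exactly one species", call. = FALSE)
  structure(list(name = name, reactions = reactions,
                 export_reaction_id = export_reaction_id,
                 new_metabolites = new_metabolites),
            class = "pathway_definition")
}

#' Graft a heterologous pathway onto a model
#'
#' Adds the pathway reactions and export reaction. The objective is *not*
#' changed; scenario configuration decides what to optimize. The model id is
#' annotated as `<model_id>_<pathway name>`.
#'
#' @param model A (curated) metabolic model.
#' @param pathway A [pathway_definition()].
#' @return The extended model; `annotations$product_export` records the
#'   export reaction id.
#' @export
add_pathway <- function(model, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  known <- c(model$metabolites$id,
             if (!is.null(pathway$new_metabolites))
               pathway$new_metabolites$id)
  for (r in pathway$reactions) {
    missing <- setdiff(names(r$stoichiometry), known)
    if (length(missing))
      stop(sprintf("pathway '%s' reaction '%s' references unknown metabolite(s): %s",
                   pathway$name, r$id, paste(missing, collapse = ", ")),
           call. = FALSE)
  }
  out <- apply_edit_set(model, edit_set(additions = pathway$reactions),
                        new_metabolites = pathway$new_metabolites)
  out$annotations$model_id <- paste0(out$annotations$model_id %||% "model",
                                     "_", pathway$name)
  out$annotations$product_export <- pathway$export_reaction_id
  out
}

#' Trophic growth condition
#'
#' Named preset of maximal uptake rates (mmol/gDW/h) for the carbon sources
#' and photons plus the matching biomass reaction. Uptake bounds are applied
#' to exchange reactions as *lower* bounds of `-uptake` (BiGG convention:
#' uptake is negative exchange flux), so an uptake of 0 forbids uptake while
#' still allowing secretion.
#'
#' @param name Condition name.
#' @param uptake_bounds Named numeric vector, exchange reaction id to
#'   maximal uptake rate.
#' @param biomass_reaction_id Biomass reaction to set as objective.
#' @return Object of class `"trophic_condition"`.
#' @export
trophic_condition <- function(name, uptake_bounds, biomass_reaction_id) {
  stopifnot(is.numeric(uptake_bounds), !is.null(names(uptake_bounds)),
            all(uptake_bounds >= 0))
  structure(list(name = name, uptake_bounds = uptake_bounds,
                 biomass_reaction_id = biomass_reaction_id),
            class = "trophic_condition")
}

#' Autotrophic condition preset for iJN678-style models
#'
#' Inorganic carbon on bicarbonate only (3.7 mmol/gDW/h), no CO2 or glucose
#' uptake, light-limited photon supply of 45 mmol/gDW/h, autotrophic biomass
#' composition.
#'
#' @return A [trophic_condition()].
#' @export
autotrophic_condition <- function() {
  trophic_condition("autotrophic",
                    c(EX_co2_e = 0, EX_hco3_e = 3.7, EX_glc__D_e = 0,
                      EX_photon_e = 45),
                    "BIOMASS_Ec_SynAuto")
}

#' Mixotrophic condition preset for iJN678-style models
#'
#' Glucose at 0.38 mmol/gDW/h, no inorganic carbon uptake, photon supply of
#' 45 mmol/gDW/h, mixotrophic biomass composition.
#'
#' @return A [trophic_condition()].
#' @export
mixotrophic_condition <- function() {
  trophic_condition("mixotrophic",
                    c(EX_co2_e = 0, EX_hco3_e = 0, EX_glc__D_e = 0.38,
                      EX_photon_e = 45),
                    "BIOMASS_Ec_SynMixo")
}

#' Apply a trophic condition to a model
#'
#' Sets each listed exchange's lower bound to minus its maximal uptake and
#' makes the condition's biomass reaction the (sole) objective. Idempotent.
#' The scenario layer may subsequently override the objective with a product
#' export reaction.
#'
#' @param model A metabolic model.
#' @param condition A [trophic_condition()].
#' @return The constrained model; `annotations$trophic` records the name.
#' @export
set_trophic_condition <- function(model, condition) {
  stopifnot(inherits(condition, "trophic_condition"))
  ids <- names(condition$uptake_bounds)
  missing <- setdiff(c(ids, condition$biomass_reaction_id),
                     model$reactions$id)
  if (length(missing))
    stop("condition references unknown reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- model
  for (id in ids)
    out <- set_bounds(out, id, lb = -condition$uptake_bounds[[id]])
  out <- set_objective(out, condition$biomass_reaction_id)
  out$annotations$trophic <- condition$name
  out
}

parse_stoich_string <- function(s) {
  if (is.null(s) || !nzchar(s)) return(stats::setNames(numeric(0),
                                                       character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed stoichiometry string: ", s, call. = FALSE)
  stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2L)),
                  vapply(kv, `[`, character(1), 1L))
}

stoich_to_string <- function(st) {
  if (!length(st)) return("")
  paste(names(st), format(unname(st), digits = 17, trim = TRUE,
                          scientific = FALSE), sep = ":", collapse = ";")
}

reaction_from_record <- function(rec) {
  reaction(id = rec$id,
           stoichiometry = parse_stoich_string(rec$stoichiometry),
           lb = num_or_inf(rec$lb), ub = num_or_inf(rec$ub),
           name = rec$name %||% rec$id,
           gene_associated = isTRUE(rec$gene_associated) ||
             identical(rec$gene_associated, "TRUE"),
           subsystem = rec$subsystem %||% "")
}

num_or_inf <- function(x) {
  if (is.numeric(x)) return(x)
  x <- as.character(x)
  if (x %in% c("Inf", "inf")) Inf else if (x %in% c("-Inf", "-inf")) -Inf
  else as.numeric(x)
}

#' Read a curation or pathway config file
#'
#' YAML with optional sections `metabolites` (id/name/compartment/formula/
#' charge), `additions` (reaction records with stoichiometry strings
#' `"met:coeff;met:coeff"`), `bound_changes` (`id`, `lb`, `ub`), `removals`,
#' and for pathway files `name` and `export_reaction_id`.
#'
#' @param path File path.
#' @return For pathway files (with `export_reaction_id`) a
#'   [pathway_definition()]; otherwise a list with `edits` ([edit_set()]),
#'   `metabolites`, `model_id`, and `atpm` (flux floor or `NULL`).
#' @export
read_curation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mets <- NULL
  if (!is.null(cfg$metabolites))
    mets <- do.call(rbind, lapply(cfg$metabolites, function(m)
      metabolite(m$id, m$name %||% m$id, m$compartment,
                 m$formula %||% "", m$charge %||% 0L)))
  adds <- lapply(cfg$additions %||% list(), reaction_from_record)
  es <- edit_set(additions = adds,
                 bound_changes = cfg$bound_changes,
                 removals = unlist(cfg$removals) %||% character(0))
  if (!is.null(cfg$export_reaction_id)) {
    return(pathway_definition(cfg$name, adds, cfg$export_reaction_id,
                              new_metabolites = mets))
  }
  list(edits = es, metabolites = mets,
       model_id = cfg$model_id %||% NULL,
       atpm = cfg$atpm$flux_floor %||% NULL)
}

#' Build the curated iJN678_AK model from a base model and config
#'
#' Applies the shipped (or user-supplied) declarative curation config to an
#' iJN678-shaped base model: TCA shunts, phosphoketolase, Entner-Doudoroff
#' pathway, light-independent serine biosynthesis, prephenate/arogenate
#' reactions, alternative electron routes (NDH-2, alternative terminal
#' oxidase, flavodiiron proteins), transhydrogenase reversibility handling,
#' zero-constraints on cytochrome b6f / cytochrome c oxidase / NAD(P)H
#' dehydrogenase and on LEUTAi/GLYCL/GLYCL_2, the three-reaction glycine
#' cleavage replacement, and the ATPM maintenance reaction. Any single edit
#' failure aborts with the offending edit named.
#'
#' @param base_model The base genome-scale model.
#' @param curation_config Path to the config file; defaults to the shipped
#'   transcription (`system.file("extdata/curation/ijn678_ak.yaml")`).
#' @return Curated model annotated with the config's model id; the applied
#'   edit list is in `attr(, "curation_report")`.
#' @export
build_ijn678_ak <- function(base_model,
                            curation_config = system.file(
                              "extdata", "curation", "ijn678_ak.yaml",
                              package = "cyanoflux")) {
  cfg <- read_curation_config(curation_config)
  out <- apply_edit_set(base_model, cfg$edits,
                        new_metabolites = cfg$metabolites)
  rep1 <- attr(out, "curation_report")
  if (!is.null(cfg$atpm)) {
    out2 <- add_atpm(out, flux_floor = cfg$atpm)
    attr(out2, "curation_report") <- rbind(rep1, data.frame(
      edit = "addition", id = "ATPM", detail = "atpm", stringsAsFactors = FALSE))
    out <- out2
  }
  if (!is.null(cfg$model_id)) out$annotations$model_id <- cfg$model_id
  out
}

#' Load one of the shipped alkene pathway definitions
#'
#' The four heterologous alkene routes (isoprene via isoprene synthase from
#' DMAPP, isobutene via decarboxylation of 3-methyl-2-oxobutanoate, ethylene
#' via the ethylene-forming enzyme from 2-oxoglutarate, 1-undecene via
#' oxidative decarbonylation of dodecanoate), each with a cytoplasmic export
#' pseudo-reaction intended to act as production objective. Stoichiometries
#' are a synthetic transcription using literature-standard chemistry and are
#' fully overridable by user-supplied files.
#'
#' @param name One of `"isoprene"`, `"isobutene"`, `"ethylene"`,
#'   `"undecene"`.
#' @return A [pathway_definition()].
#' @export
shipped_pathway <- function(name = c("isoprene", "isobutene", "ethylene",
                                     "undecene")) {
  name <- match.arg(name)
  read_curation_config(system.file("extdata", "pathways",
                                   paste0(name, ".yaml"),
                                   package = "cyanoflux"))
}
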