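#' Export a flux state as flat JSON
#'
#' Writes `{"reaction_id": flux, ...}`, the shape map-overlay tools consume.
#'
#' @param fs A [flux_state()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_flux_json <- function(fs, path) {
  vals <- as.list(fs$fluxes)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a flux state as TSV
#'
#' Machine-readable full-precision table (reaction, flux). Presentation
#' tables derived from it round to 2 decimals with the `<0.01`
#' display-zero rule; this file keeps exact values.
#'
#' @param fs A [flux_state()].
#' @param path Output path.
#' @param manifest Optional named list written as `# key: value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(fs, path, manifest = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(manifest))
    writeLines(sprintf("# %s: %s", names(manifest),
                       vapply(manifest, as.character, character(1))), con)
  writeLines("reaction\tflux", con)
  writeLines(sprintf("%s\t%.12g", names(fs$fluxes), fs$fluxes), con)
  invisible(path)
}

scenario_manifest <- function(model, scen, method) {
  list(model = model$annotations$model_id %||% "model",
       model_hash = model_hash(model),
       scenario = scen$name %||% "scenario",
       objective = scen$objective,
       method = method,
       loopless = isTRUE(scen$loopless),
       two_step_fraction = scen$two_step$fraction %||% NA,
       fva_fraction = scen$fva$fraction %||% NA,
       tool = paste0("cyanoflux ",
                     as.character(utils::packageVersion("cyanoflux"))))
}

#' Run the full analysis pipeline from a config file
#'
#' Orchestrates, per scenario: model loading, optional curation, optional
#' pathway grafting, trophic-condition constraints, optimization (pFBA or
#' two-step biomass-coupled production, optional loopless correction),
#' flux-sum/cofactor reports, producer-consumer tables, yields, and optional
#' FVA and phase-plane scans. Each scenario writes its own file bundle under
#' `out_dir`; a failure aborts that scenario with the stage named while
#' other scenarios continue.
#'
#' Config (YAML): `model` (`path` + `dialect`), optional `curation` (path),
#' optional `pathway` (shipped name or path), `out_dir`, and a `scenarios`
#' list, each with `name`, `objective` (reaction id or `"biomass"`),
#' optional `trophic` (preset name `autotrophic`/`mixotrophic`, or a map
#' with `uptake_bounds` + `biomass_reaction_id`), optional `two_step`
#' (`target`, `fraction`), `loopless` flag, optional `fva` (`fraction`),
#' `fluxsum_metabolites`, optional `yields` (product/substrate ids),
#' optional `phase_plane` (`rxn_x`, `rxn_y`, `n_points`).
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Named list per scenario: `flux_state`, `cofactors`, `tables`,
#'   `yields`, `fva`, `phase_plane`, `manifest`, or an error condition for
#'   failed scenarios. Invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$model$path))
    stop("config must name an input model path", call. = FALSE)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir configured",
                                                call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dialect <- cfg$model$dialect %||% "native"
  base <- if (identical(dialect, "sbml")) read_sbml(cfg$model$path)
          else read_model(cfg$model$path)
  if (!is.null(cfg$curation))
    base <- build_ijn678_ak(base, cfg$curation)
  if (!is.null(cfg$pathway)) {
    pw <- if (file.exists(cfg$pathway)) read_curation_config(cfg$pathway)
          else shipped_pathway(cfg$pathway)
    base <- add_pathway(base, pw)
  }
  write_model(base, file.path(out_dir, "curated_model"), dialect = "native")

  results <- list()
  for (scen in cfg$scenarios) {
    nm <- scen$name %||% "scenario"
    res <- tryCatch(run_scenario(base, scen, out_dir),
                    error = function(e) {
                      message(sprintf("scenario '%s' failed: %s", nm,
                                      conditionMessage(e)))
                      e
                    })
    results[[nm]] <- res
  }
  invisible(results)
}

resolve_trophic <- function(scen) {
  tr <- scen$trophic
  if (is.null(tr)) return(NULL)
  if (is.character(tr)) {
    return(switch(tr,
                  autotrophic = autotrophic_condition(),
                  mixotrophic = mixotrophic_condition(),
                  stop("unknown trophic preset: ", tr, call. = FALSE)))
  }
  trophic_condition(tr$name %||% "custom",
                    unlist(tr$uptake_bounds),
                    tr$biomass_reaction_id)
}

run_scenario <- function(base, scen, out_dir) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  model <- base
  cond <- resolve_trophic(scen)
  if (!is.null(cond))
    model <- stage("trophic", set_trophic_condition(model, cond))
  objective <- scen$objective %||% names(model$objective)[1]
  if (identical(objective, "biomass") && !is.null(cond))
    objective <- cond$biomass_reaction_id

  fs <- if (!is.null(scen$two_step)) {
    stage("two_step", two_step_optimize(
      model,
      biomass_id = scen$two_step$biomass %||% cond$biomass_reaction_id,
      target_id = scen$two_step$target %||% objective,
      biomass_fraction = scen$two_step$fraction %||% 0.10))
  } else {
    stage("pfba", pfba(model, objective))
  }
  if (isTRUE(scen$loopless))
    fs <- stage("loopless", remove_loops(model, fs))

  nm <- scen$name %||% "scenario"
  man <- scenario_manifest(model, scen, fs$method)
  prefix <- file.path(out_dir, nm)
  write_flux_tsv(fs, paste0(prefix, "_fluxes.tsv"), manifest = man)
  export_flux_json(fs, paste0(prefix, "_fluxes.json"))

  mets <- unlist(scen$fluxsum_metabolites %||%
                   list("atp_c", "nadph_c", "nadh_c"))
  mets <- intersect(mets, model$metabolites$id)
  tables <- lapply(mets, function(m)
    stage(paste0("fluxsum:", m),
          producer_consumer_table(model, fs, m)))
  names(tables) <- mets
  for (m in mets) {
    tb <- as.data.frame(tables[[m]])
    tb <- cbind(metabolite = rep(m, nrow(tb)), tb)
    utils::write.table(tb, paste0(prefix, "_fluxsum_", m, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cof <- if (all(c("atp_c", "nadph_c", "nadh_c") %in%
                   model$metabolites$id))
    stage("cofactors", cofactor_report(model, fs)) else NULL

  yl <- NULL
  if (!is.null(scen$yields)) {
    y <- scen$yields
    yl <- stage("yields", yields(
      model, fs, product_id = y$product_id,
      product_flux_id = y$product_flux_id %||% objective,
      substrate_exchange_ids = unlist(y$substrate_exchange_ids),
      substrate_id = y$substrate_id))
  }
  fv <- NULL
  if (!is.null(scen$fva)) {
    fv <- stage("fva", fva(model, objective,
                           fraction = scen$fva$fraction %||% 0.95,
                           loopless = isTRUE(scen$loopless)))
    utils::write.table(as.data.frame(fv), paste0(prefix, "_fva.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pp <- NULL
  if (!is.null(scen$phase_plane)) {
    p <- scen$phase_plane
    pp <- stage("phase_plane", phenotypic_phase_plane(
      model, p$rxn_x, p$rxn_y, n_points = p$n_points %||% 50L))
    utils::write.table(as.data.frame(pp),
                       paste0(prefix, "_phase_plane.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(man, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(flux_state = fs, cofactors = cof, tables = tables, yields = yl,
       fva = fv, phase_plane = pp, manifest = man)
}
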