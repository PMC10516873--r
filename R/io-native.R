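#' Write a model to disk
#'
#' Two dialects. `"native"`: a directory holding `metabolites.tsv` (id,
#' name, compartment, formula, charge), `reactions.tsv` (id, name,
#' stoichiometry encoded `"met:coeff;met:coeff"`, lb, ub, objective
#' coefficient, gene_associated, subsystem) and a `model.json` header (model
#' id, annotations). `"sbml"`: a single SBML Level 3 + fbc file. Both
#' round-trip losslessly through [read_model()] / [read_sbml()] for all
#' fields above.
#'
#' @param model A metabolic model.
#' @param path Directory (native) or file path (sbml).
#' @param dialect `"native"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("native", "sbml")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  if (dialect == "sbml") return(write_sbml(model, path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  utils::write.table(model$metabolites,
                     file.path(path, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  obj <- stats::setNames(rep(0, n_reactions(model)), model$reactions$id)
  obj[names(model$objective)] <- unname(model$objective)
  rx <- data.frame(
    id = model$reactions$id,
    name = model$reactions$name,
    stoichiometry = vapply(model$stoichiometry, stoich_to_string,
                           character(1)),
    lb = format_bound(model$reactions$lb),
    ub = format_bound(model$reactions$ub),
    objective_coefficient = unname(obj),
    gene_associated = model$reactions$gene_associated,
    subsystem = model$reactions$subsystem,
    stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(path, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(model$annotations, file.path(path, "model.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

format_bound <- function(x) {
  ifelse(is.finite(x), format(x, digits = 17, trim = TRUE,
                              scientific = FALSE),
         ifelse(x > 0, "Inf", "-Inf"))
}

#' Read a model in the native tabular dialect
#'
#' Inverse of [write_model()] with `dialect = "native"`.
#'
#' @param path Directory containing `metabolites.tsv`, `reactions.tsv`,
#'   `model.json`.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path) {
  mfile <- file.path(path, "metabolites.tsv")
  rfile <- file.path(path, "reactions.tsv")
  if (!file.exists(mfile) || !file.exists(rfile))
    stop("not a native model directory: ", path, call. = FALSE)
  mets <- utils::read.table(mfile, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "character", "character",
                                           "integer"),
                            quote = "", comment.char = "")
  mets$formula[is.na(mets$formula)] <- ""
  rx <- utils::read.table(rfile, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "character", "numeric", "logical",
                                         "character"),
                          quote = "", comment.char = "")
  rx$stoichiometry[is.na(rx$stoichiometry)] <- ""
  rx$subsystem[is.na(rx$subsystem)] <- ""
  reactions <- lapply(seq_len(nrow(rx)), function(k)
    reaction(rx$id[k], parse_stoich_string(rx$stoichiometry[k]),
             lb = num_or_inf(rx$lb[k]), ub = num_or_inf(rx$ub[k]),
             name = rx$name[k], gene_associated = rx$gene_associated[k],
             subsystem = rx$subsystem[k]))
  obj <- stats::setNames(rx$objective_coefficient, rx$id)
  obj <- obj[obj != 0]
  ann <- if (file.exists(file.path(path, "model.json")))
    jsonlite::read_json(file.path(path, "model.json"), simplifyVector = TRUE)
  else list(model_id = basename(path))
  metabolic_model(mets, reactions, objective = obj, annotations = ann)
}
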