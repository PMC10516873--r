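# SBML Level 3 Version 1 + fbc version 2 reader/writer.
# Covers the constraint-based subset: compartments, species (with fbc
# charge/chemicalFormula), reactions (reactants/products, fbc flux-bound
# parameters, geneProductAssociation presence), global parameters and the
# active fbc objective. Groups/layout/annotation payloads are ignored.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read an SBML Level 3 (fbc) model
#'
#' Parses species, reactions, flux bounds and the active objective from an
#' SBML file as distributed by the BiGG database. A reaction is flagged
#' `gene_associated` iff it carries any `fbc:geneProductAssociation`.
#' A file with species but no reactions yields a valid model with a warning.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("cannot read SBML file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing"))
    stop("not an SBML Level 3 document: no <model> element", call. = FALSE)

  params <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  spp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  if (length(spp) == 0L) stop("SBML file contains no species", call. = FALSE)
  strip_prefix <- function(x) sub("^(M_|R_)", "", x)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(spp, "id")),
    name = ifelse(is.na(xml2::xml_attr(spp, "name")), "",
                  xml2::xml_attr(spp, "name")),
    compartment = xml2::xml_attr(spp, "compartment"),
    formula = ifelse(is.na(xml2::xml_attr(spp, "fbc:chemicalFormula", ns = ns)), "",
                     xml2::xml_attr(spp, "fbc:chemicalFormula", ns = ns)),
    charge = ifelse(is.na(xml2::xml_attr(spp, "fbc:charge", ns = ns)), 0L,
                    suppressWarnings(as.integer(
                      xml2::xml_attr(spp, "fbc:charge", ns = ns)))),
    stringsAsFactors = FALSE)

  rxns <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxns) == 0L)
    warning("SBML file contains no reactions", call. = FALSE)
  bound_of <- function(node, attrname, default) {
    ref <- xml2::xml_attr(node, attrname, ns = ns)
    if (is.na(ref)) {
      stop(sprintf("reaction '%s' lacks fbc %s", xml2::xml_attr(node, "id"),
                   attrname), call. = FALSE)
    }
    if (!ref %in% names(pvals))
      stop("flux bound parameter not found: ", ref, call. = FALSE)
    pvals[[ref]]
  }
  reactions <- lapply(rxns, function(node) {
    id <- strip_prefix(xml2::xml_attr(node, "id"))
    reac <- xml2::xml_find_all(node,
                               "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(node,
                               "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(reac, "species"))),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(prod, "species"))))
    if (length(st)) st <- tapply(st, names(st), sum)[unique(names(st))]
    else st <- stats::setNames(numeric(0), character(0))
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    nm <- xml2::xml_attr(node, "name")
    reaction(id, st,
             lb = bound_of(node, "fbc:lowerFluxBound"),
             ub = bound_of(node, "fbc:upperFluxBound"),
             name = if (is.na(nm)) "" else nm,
             gene_associated = !inherits(gpa, "xml_missing"),
             subsystem = "")
  })

  obj <- numeric(0)
  lo <- xml2::xml_find_first(mod, ".//fbc:listOfObjectives", ns)
  if (!inherits(lo, "xml_missing")) {
    active <- xml2::xml_attr(lo, "fbc:activeObjective", ns = ns)
    objs <- xml2::xml_find_all(lo, "./fbc:objective", ns)
    pick <- if (!is.na(active))
      objs[xml2::xml_attr(objs, "fbc:id", ns = ns) == active] else objs
    if (length(pick)) {
      fo <- xml2::xml_find_all(pick[[1]],
                               "./fbc:listOfFluxObjectives/fbc:fluxObjective",
                               ns)
      obj <- stats::setNames(
        as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns = ns)),
        strip_prefix(xml2::xml_attr(fo, "fbc:reaction", ns = ns)))
    }
  }
  if (!length(obj) && length(rxns) > 0)
    stop("SBML file has no fbc objective", call. = FALSE)

  mid <- xml2::xml_attr(mod, "id")
  metabolic_model(mets, reactions, objective = obj,
                  annotations = list(model_id = if (is.na(mid)) "model"
                                     else mid))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a model as SBML Level 3 + fbc
#'
#' Emits prefixed BiGG-style ids (`M_`, `R_`), per-reaction flux-bound
#' parameters, one synthetic gene product per gene-associated reaction (so
#' the flag round-trips), and the model objective as the active fbc
#' objective.
#'
#' @param model A metabolic model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write SBML file: ", path, call. = FALSE)
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
    SBML_NS, FBC_NS)
  w('  <model id="%s" fbc:strict="true">',
    xml_escape(model$annotations$model_id %||% "model"))

  comps <- unique(model$metabolites$compartment)
  w('    <listOfCompartments>')
  for (cp in comps)
    w('      <compartment id="%s" constant="true"/>', xml_escape(cp))
  w('    </listOfCompartments>')

  w('    <listOfSpecies>')
  for (k in seq_len(n_metabolites(model))) {
    m <- model$metabolites[k, ]
    frm <- if (nzchar(m$formula))
      sprintf(' fbc:chemicalFormula="%s"', xml_escape(m$formula)) else ""
    w(paste0('      <species id="M_%s" name="%s" compartment="%s"',
             ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false" fbc:charge="%d"%s/>'),
      m$id, xml_escape(m$name), xml_escape(m$compartment), m$charge, frm)
  }
  w('    </listOfSpecies>')

  w('    <listOfParameters>')
  for (k in seq_len(n_reactions(model))) {
    r <- model$reactions[k, ]
    lbv <- if (is.finite(r$lb)) num(r$lb) else "-INF"
    ubv <- if (is.finite(r$ub)) num(r$ub) else "INF"
    w('      <parameter id="R_%s_lb" value="%s" constant="true"/>', r$id, lbv)
    w('      <parameter id="R_%s_ub" value="%s" constant="true"/>', r$id, ubv)
  }
  w('    </listOfParameters>')

  gene_rxns <- model$reactions$id[model$reactions$gene_associated]
  if (length(gene_rxns)) {
    w('    <fbc:listOfGeneProducts>')
    for (id in gene_rxns)
      w('      <fbc:geneProduct fbc:id="G_%s" fbc:label="G_%s"/>', id, id)
    w('    </fbc:listOfGeneProducts>')
  }

  w('    <listOfReactions>')
  for (k in seq_len(n_reactions(model))) {
    r <- model$reactions[k, ]
    st <- model$stoichiometry[[k]]
    w(paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="R_%s_lb" fbc:upperFluxBound="R_%s_ub">'),
      r$id, xml_escape(r$name), if (r$lb < 0) "true" else "false",
      r$id, r$id)
    cons <- st[st < 0]; prods <- st[st > 0]
    if (length(cons)) {
      w('        <listOfReactants>')
      for (mn in names(cons))
        w('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          mn, num(-cons[[mn]]))
      w('        </listOfReactants>')
    }
    if (length(prods)) {
      w('        <listOfProducts>')
      for (mn in names(prods))
        w('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          mn, num(prods[[mn]]))
      w('        </listOfProducts>')
    }
    if (r$gene_associated) {
      w('        <fbc:geneProductAssociation>')
      w('          <fbc:geneProductRef fbc:geneProduct="G_%s"/>', r$id)
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')

  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  for (id in names(model$objective))
    w('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
      id, num(model$objective[[id]]))
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
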