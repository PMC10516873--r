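Package: cyanoflux
Title: Constraint-Based Analysis of Energy and Redox Metabolism in
    Cyanobacterial Production Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stoichiometric (constraint-based) modelling of
    photoautotrophic metabolism, built around genome-scale models of
    Synechocystis sp. PCC 6803 engineered for alkene production. Provides a
    core metabolic-model data structure with SBML (Level 3 + fbc) and native
    tabular readers/writers, declarative model curation and heterologous
    pathway grafting, flux balance analysis (FBA), parsimonious FBA, flux
    variability analysis, loopless flux correction, two-step biomass-coupled
    production optimization, phenotypic phase planes, metabolite-centric
    flux-sum (turnover) analysis with cofactor producer/consumer breakdowns,
    and productivity/mass-yield/c-mol-yield reporting. Small synthetic
    networks with known analytic optima are included so every stage is
    testable without external model downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
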