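test_that("edit sets apply purely: additions, ordered bound changes, removals", {
  m <- mini_base_model()
  lb_before <- m$reactions$lb
  es <- edit_set(
    additions = list(reaction("NEW", c(akg_c = -1, succ_c = 1))),
    bound_changes = data.frame(id = c("NADTRHD", "NADTRHD"),
                               lb = c(-1000, 0), ub = c(1000, 0)),
    removals = "CBFCum")
  out <- apply_edit_set(m, es)
  # input untouched
  expect_identical(m$reactions$lb, lb_before)
  expect_true("NEW" %in% out$reactions$id)
  expect_false("CBFCum" %in% out$reactions$id)
  # sequential bound edits: reversible first, then pinned closed
  idx <- match("NADTRHD", out$reactions$id)
  expect_equal(out$reactions$lb[idx], 0)
  expect_equal(out$reactions$ub[idx], 0)
  # inverse bound change restores the original
  back <- apply_edit_set(out, edit_set(bound_changes = data.frame(
    id = "NADTRHD", lb = 0, ub = 1000)))
  expect_equal(back$reactions$lb[match("NADTRHD", back$reactions$id)],
               m$reactions$lb[match("NADTRHD", m$reactions$id)])
  # identity edit
  expect_equal(apply_edit_set(m, edit_set())$reactions, m$reactions)
})

test_that("edit sets reject collisions and dangling ids by name", {
  m <- mini_base_model()
  expect_error(apply_edit_set(m, edit_set(additions = list(
    reaction("NADTRHD", c(akg_c = -1, succ_c = 1))))), "NADTRHD")
  expect_error(apply_edit_set(m, edit_set(bound_changes = data.frame(
    id = "TYPO_ID", lb = 0, ub = 0))), "TYPO_ID")
})

test_that("ATPM is installed with the canonical hydrolysis stoichiometry", {
  toy <- make_phototroph_toy()
  base <- apply_edit_set(toy, edit_set(removals = "ATPM"))
  withm <- add_atpm(base, flux_floor = 0)
  S <- stoichiometric_matrix(withm)
  col <- S[, "ATPM"]
  expect_equal(col[["atp_c"]], -1)
  expect_equal(col[["h2o_c"]], -1)
  expect_equal(col[["adp_c"]], 1)
  expect_equal(col[["pi_c"]], 1)
  expect_equal(col[["h_c"]], 1)
  idx <- match("ATPM", withm$reactions$id)
  expect_false(withm$reactions$gene_associated[idx])
  expect_equal(withm$reactions$lb[idx], 0)
  # a zero maintenance floor does not perturb the optimum
  expect_equal(fba(withm, "BIOMASS")$objective_value,
               fba(base, "BIOMASS")$objective_value, tolerance = 1e-9)
  expect_error(add_atpm(withm), "ATPM")
  nosp <- make_linear_chain(2, 5)
  expect_error(add_atpm(nosp), "atp_c")
})

test_that("pathway grafting adds reactions and export without touching the objective", {
  toy <- make_phototroph_toy()
  pw <- pathway_definition(
    "toyene",
    reactions = list(
      reaction("TOYS", c(cx_c = -1, alkene_c = 1), gene_associated = TRUE),
      reaction("EX_alkene_c", c(alkene_c = -1), gene_associated = FALSE)),
    export_reaction_id = "EX_alkene_c",
    new_metabolites = metabolite("alkene_c", formula = "CH2"))
  out <- add_pathway(toy, pw)
  expect_true(all(c("TOYS", "EX_alkene_c") %in% out$reactions$id))
  expect_equal(out$objective, toy$objective)
  expect_equal(out$annotations$model_id, "phototroph_toy_toyene")
  expect_equal(out$annotations$product_export, "EX_alkene_c")
  expect_equal(fba(out, "BIOMASS")$status, "optimal")
  # export must drain exactly one species
  expect_error(pathway_definition("bad", list(
    reaction("EX_x", c(cx_c = -1, alkene_c = -1),
             gene_associated = FALSE)), "EX_x"), "exactly one")
  # unknown precursor is refused
  bad <- pathway_definition("orphan", list(
    reaction("OR1", c(ghost_c = -1, alkene2_c = 1)),
    reaction("EX_alkene2_c", c(alkene2_c = -1), gene_associated = FALSE)),
    "EX_alkene2_c",
    new_metabolites = metabolite("alkene2_c"))
  expect_error(add_pathway(toy, bad), "ghost_c")
})

test_that("all four shipped alkene pathways parse and carry one export drain each", {
  for (nm in c("isoprene", "isobutene", "ethylene", "undecene")) {
    pw <- shipped_pathway(nm)
    expect_s3_class(pw, "pathway_definition")
    ids <- vapply(pw$reactions, function(r) r$id, character(1))
    expect_true(pw$export_reaction_id %in% ids)
    exp_st <- pw$reactions[[match(pw$export_reaction_id,
                                  ids)]]$stoichiometry
    expect_length(exp_st, 1)
    expect_lt(exp_st[[1]], 0)
  }
})

test_that("trophic conditions set uptake as negative exchange lower bounds, idempotently", {
  toy <- make_phototroph_toy()
  cond <- trophic_condition("toy_auto",
                            c(EX_co2_e = 3.7, EX_photon_e = 45),
                            "BIOMASS")
  out <- set_trophic_condition(toy, cond)
  expect_equal(out$reactions$lb[out$reactions$id == "EX_co2_e"], -3.7)
  expect_equal(out$reactions$lb[out$reactions$id == "EX_photon_e"], -45)
  expect_equal(out$objective, c(BIOMASS = 1))
  expect_identical(set_trophic_condition(out, cond)$reactions,
                   out$reactions)
  # uptake 0 forbids uptake but leaves secretion open
  cond0 <- trophic_condition("noc", c(EX_co2_e = 0), "BIOMASS")
  shut <- set_trophic_condition(toy, cond0)
  expect_equal(shut$reactions$lb[shut$reactions$id == "EX_co2_e"], 0)
  expect_gt(shut$reactions$ub[shut$reactions$id == "EX_co2_e"], 0)
  expect_error(set_trophic_condition(toy, autotrophic_condition()),
               "EX_hco3_e")
})

test_that("carbon uptake under a carbon-capped condition never exceeds the cap", {
  toy <- make_phototroph_toy()
  cond <- trophic_condition("capped", c(EX_co2_e = 3.7), "BIOMASS")
  m <- set_trophic_condition(toy, cond)
  fs <- pfba(m, "BIOMASS")
  # CO2 is the sole carbon source and carries one carbon
  expect_lte(-fs$fluxes[["EX_co2_e"]], 3.7 + 1e-9)
  expect_equal(fs$objective_value, 3.7, tolerance = 1e-6)  # carbon-limited
})

test_that("the shipped genome-scale curation config builds against a conforming base", {
  base <- mini_base_model()
  cur <- build_ijn678_ak(base)
  expect_gt(n_reactions(cur), n_reactions(base))
  for (id in c("NADTRHD", "LEUTAi", "GLYCL", "GLYCL_2", "CBFCum",
               "CYO1b2um", "NDH1um")) {
    idx <- match(id, cur$reactions$id)
    expect_equal(cur$reactions$lb[idx], 0)
    expect_equal(cur$reactions$ub[idx], 0)
  }
  expect_true(all(c("PKETF", "PKETX", "EDD", "EDA", "PGCD", "PSERT",
                    "PSP_L", "GLYCLa", "GLYCLb", "GLYCLc", "ATPM") %in%
                    cur$reactions$id))
  expect_equal(cur$annotations$model_id, "iJN678_AK")
  rep <- attr(cur, "curation_report")
  expect_true(is.data.frame(rep) && nrow(rep) > 20)
  # constrained reactions cannot carry flux in any subsequent optimum
  fs <- fba(set_objective(cur, "PKETF"), "PKETF")
  if (fs$status == "optimal")
    expect_flux_equal(fs$fluxes[c("LEUTAi", "GLYCL", "GLYCL_2")],
                      rep(0, 3))
  # re-applying collides
  expect_error(build_ijn678_ak(cur), "collide")
})

test_that("a misspelled id in a curation config aborts naming the offender", {
  base <- mini_base_model()
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model_id: broken",
               "bound_changes:",
               "  - {id: NADTRHDX, lb: 0, ub: 0}"), cfgfile)
  expect_error(build_ijn678_ak(base, cfgfile), "NADTRHDX")
})

test_that("shipped curation additions are elementally clean where formulas permit", {
  base <- mini_base_model()
  cur <- build_ijn678_ak(base)
  rep <- attr(cur, "curation_report")
  adds <- rep[rep$edit == "addition", ]
  expect_false(any(adds$detail == "imbalanced"))
})
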