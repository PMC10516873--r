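test_that("elemental formulas parse to count maps and reject junk", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6),
               ignore_attr = TRUE)
  expect_named(parse_formula("C6H12O6"), c("C", "H", "O"))
  expect_equal(parse_formula("C5H8"), c(C = 5, H = 8), ignore_attr = TRUE)
  expect_length(parse_formula(""), 0)
  expect_equal(parse_formula("CH2O"), c(C = 1, H = 2, O = 1),
               ignore_attr = TRUE)
  expect_equal(unname(parse_formula("C10H12MgN5O13P")[["Mg"]]), 1)
  # repeated element symbols accumulate
  expect_equal(unname(parse_formula("CH3CH3")[["C"]]), 2)
  expect_error(parse_formula("C6h12"), "position 3")
  expect_error(parse_formula("1C6"), "position 1")
  expect_error(parse_formula("C0"), "non-positive")
})

test_that("mass balance check reports balanced, imbalanced, boundary and unverifiable", {
  mets <- rbind(metabolite("a_c", formula = "C"),
                metabolite("b_c", formula = "C"),
                metabolite("c2_c", formula = "C2"),
                metabolite("u_c", formula = ""))
  rxns <- list(reaction("OK", c(a_c = -1, b_c = 1)),
               reaction("BAD", c(c2_c = -1, b_c = 1)),
               reaction("EX_a", c(a_c = -1), gene_associated = FALSE),
               reaction("UNK", c(u_c = -1, b_c = 1)))
  m <- metabolic_model(mets, rxns, objective = c(OK = 1))
  expect_equal(check_mass_balance("OK", m)$status, "balanced")
  bad <- check_mass_balance("BAD", m)
  expect_equal(bad$status, "imbalanced")
  expect_equal(unname(bad$imbalance[["C"]]), -1)
  expect_equal(check_mass_balance("EX_a", m)$status, "boundary")
  expect_equal(check_mass_balance("UNK", m)$status, "unverifiable")
  expect_error(check_mass_balance("NOPE", m), "unknown reaction")
})

test_that("stoichiometric matrix lays out coefficients by metabolite and reaction order", {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  m <- metabolic_model(mets, list(
    reaction("EX_a", c(a_c = -1), lb = -5, gene_associated = FALSE),
    reaction("R", c(a_c = -1, b_c = 1)),
    reaction("EX_b", c(b_c = -1), gene_associated = FALSE)),
    objective = c(EX_b = 1))
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(as.numeric(S[, "R"]), c(-1, 1))
  expect_equal(rownames(S), c("a_c", "b_c"))
  # degenerate: model with no reactions
  empty <- metabolic_model(metabolite("x_c"), list(), objective = numeric(0))
  expect_equal(dim(stoichiometric_matrix(empty)), c(1L, 0L))
})

test_that("S %*% v reproduces per-metabolite net rates computed by direct summation", {
  for (seed in 1:5) {
    m <- make_random_feasible(5, 9, seed)
    v <- attr(m, "planted_flux")
    S <- stoichiometric_matrix(m)
    direct <- vapply(m$metabolites$id, function(met) {
      s <- 0
      for (j in seq_len(n_reactions(m))) {
        st <- m$stoichiometry[[j]]
        if (met %in% names(st)) s <- s + st[[met]] * v[[j]]
      }
      s
    }, numeric(1))
    expect_flux_equal(as.numeric(S %*% v), unname(direct), tol = 1e-9)
  }
})

test_that("model construction enforces its invariants", {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  expect_error(reaction("R", c(a_c = -1), lb = 2, ub = 1), "lower bound")
  expect_error(metabolic_model(mets, list(
    reaction("R", c(nope_c = -1, b_c = 1))), objective = numeric(0)),
    "unknown metabolite")
  expect_error(metabolic_model(mets, list(
    reaction("R", c(a_c = -1, b_c = 1)),
    reaction("R", c(b_c = -1, a_c = 1))), objective = numeric(0)),
    "duplicate reaction ids")
  m <- metabolic_model(mets, list(reaction("R", c(a_c = -1, b_c = 1))),
                       objective = numeric(0))
  expect_error(set_objective(m, "NOPE"), "unknown reaction")
  expect_error(set_bounds(m, "R", lb = 5, ub = 1), "lb > ub")
  # irreversibility convention: irreversible iff lb >= 0
  expect_true(m$reactions$lb[1] >= 0)
})

test_that("native dialect round trip is lossless field by field", {
  toy <- make_phototroph_toy()
  d <- withr::local_tempdir()
  write_model(toy, d, "native")
  back <- read_model(d)
  expect_identical(toy$metabolites, back$metabolites)
  expect_identical(toy$reactions, back$reactions)
  expect_equal(toy$objective, back$objective)
  for (k in seq_len(n_reactions(toy)))
    expect_equal(sort(names(toy$stoichiometry[[k]])),
                 sort(names(back$stoichiometry[[k]])))
  expect_identical(model_hash(toy), model_hash(back))
})

test_that("SBML round trip preserves ids, stoichiometry, bounds, objective and gene flags", {
  models <- c(list(make_phototroph_toy(), make_linear_chain(3, 10),
                   make_internal_cycle_model(3)),
              lapply(1:5, function(s) make_random_feasible(4, 7, s)))
  for (m in models) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_model(m, f, "sbml")
    back <- read_sbml(f)
    expect_identical(m$metabolites$id, back$metabolites$id)
    expect_identical(m$metabolites$formula, back$metabolites$formula)
    expect_identical(m$reactions$id, back$reactions$id)
    expect_equal(m$reactions$lb, back$reactions$lb)
    expect_equal(m$reactions$ub, back$reactions$ub)
    expect_identical(m$reactions$gene_associated,
                     back$reactions$gene_associated)
    expect_equal(m$objective, back$objective)
    for (k in seq_len(n_reactions(m))) {
      a <- m$stoichiometry[[k]]; b <- back$stoichiometry[[k]]
      expect_equal(length(a), length(b))
      if (length(a)) expect_flux_equal(a[names(b)], b, tol = 1e-12)
    }
  }
})

test_that("SBML writer preserves negative lower bounds of reversible reactions", {
  m <- make_phototroph_toy()
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f, "sbml")
  back <- read_sbml(f)
  expect_equal(back$reactions$lb[back$reactions$id == "CO2t"], -1000)
  expect_equal(back$reactions$lb[back$reactions$id == "EX_photon_e"], -45)
})

test_that("SBML reader flags structural problems", {
  expect_error(read_sbml(withr::local_tempfile()), "cannot read")
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<notsbml><foo/></notsbml>'), f)
  expect_error(read_sbml(f), "no <model>")
})
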