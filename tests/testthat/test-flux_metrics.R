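test_that("flux-sum halves the absolute weighted flux and splits sides correctly", {
  m <- make_linear_chain(1, 2)  # EX_A -> R1 -> EX_Z at flux 2
  fs <- fba(m, "EX_Z")
  rep <- flux_sum(m, fs, "m1_c")
  expect_equal(rep$phi, 2, tolerance = 1e-9)
  expect_equal(rep$producers$id, "EX_A")   # uptake produces m1
  expect_equal(rep$consumers$id, "R1")
  expect_equal(rep$producers$percent, 100, tolerance = 1e-9)
  expect_equal(rep$consumers$percent, 100, tolerance = 1e-9)
})

test_that("an inactive metabolite has zero flux-sum and empty sides", {
  toy <- make_phototroph_toy()
  fs <- pfba(toy, "BIOMASS")
  rep <- flux_sum(toy, fs, "nadh_c")
  expect_equal(rep$phi, 0, tolerance = 1e-9)
  expect_equal(nrow(rep$producers), 0)
  expect_equal(nrow(rep$consumers), 0)
})

test_that("production equals consumption for every metabolite at steady state", {
  cases <- list(
    list(make_phototroph_toy(), "BIOMASS"),
    list(make_linear_chain(4, 6), "EX_Z"))
  for (seed in 1:5)
    cases <- c(cases, list(list(make_random_feasible(5, 9, seed), NULL)))
  for (cs in cases) {
    m <- cs[[1]]
    fs <- pfba(m, cs[[2]])
    for (met in m$metabolites$id) {
      rep <- flux_sum(m, fs, met)
      expect_equal(sum(rep$producers$contribution),
                   sum(rep$consumers$contribution), tolerance = 1e-6)
      expect_equal(sum(rep$producers$contribution), rep$phi,
                   tolerance = 1e-6)
    }
  }
})

test_that("half-absolute-sum and producer-side summation agree as independent routes", {
  toy <- make_phototroph_toy()
  fs <- pfba(toy, "BIOMASS")
  S <- as.matrix(stoichiometric_matrix(toy))
  v <- fs$fluxes[colnames(S)]
  for (met in c("atp_c", "nadph_c", "cx_c", "pi_c")) {
    rates <- S[met, ] * v
    phi_half <- 0.5 * sum(abs(rates))
    phi_prod <- sum(rates[rates > 0])
    expect_equal(phi_half, phi_prod, tolerance = 1e-8)
    expect_equal(flux_sum(toy, fs, met)$phi, phi_half, tolerance = 1e-8)
  }
})

test_that("percentages within each side total 100 for active metabolites", {
  toy <- make_phototroph_toy()
  fs <- pfba(toy, "BIOMASS")
  for (met in toy$metabolites$id) {
    rep <- flux_sum(toy, fs, met)
    if (rep$phi > 1e-8) {
      expect_equal(sum(rep$producers$percent), 100, tolerance = 0.1)
      expect_equal(sum(rep$consumers$percent), 100, tolerance = 0.1)
    }
  }
})

test_that("display threshold zeroes small entries without corrupting the bookkeeping", {
  mets <- rbind(metabolite("s_c"), metabolite("p_c"))
  m <- metabolic_model(mets, list(
    reaction("BIGIN", c(s_c = 1), lb = 0.991, ub = 0.991,
             gene_associated = FALSE),
    reaction("SMALLIN", c(s_c = 1), lb = 0.009, ub = 0.009,
             gene_associated = FALSE),
    reaction("OUT", c(s_c = -1, p_c = 1)),
    reaction("EX_p", c(p_c = -1), gene_associated = FALSE)),
    objective = c(OUT = 1))
  fs <- fba(m, "OUT")
  tb <- producer_consumer_table(m, fs, "s_c", display_threshold = 0.01)
  prod <- tb[tb$side == "producer", ]
  expect_equal(sort(prod$flux), c(0, 0.99))
  expect_equal(sum(prod$percent), 100, tolerance = 1e-6)
  expect_equal(attr(tb, "phi"), 1, tolerance = 1e-9)
})

test_that("cofactor report computes turnover and the ATP/NADPH ratio", {
  toy <- make_phototroph_toy()
  consts <- phototroph_toy_constants()
  fs <- pfba(toy, "BIOMASS")
  cr <- cofactor_report(toy, fs)
  expect_equal(unname(cr$turnover[["atp"]]), consts$atp_flux_sum,
               tolerance = 1e-6)
  expect_equal(unname(cr$turnover[["nadph"]]), consts$nadph_flux_sum,
               tolerance = 1e-6)
  expect_equal(unname(cr$turnover[["nadh"]]), 0, tolerance = 1e-9)
  expect_equal(cr$atp_nadph_ratio, consts$atp_nadph_ratio,
               tolerance = 1e-8)
  expect_error(cofactor_report(make_linear_chain(2, 5), fs), "not in model")
})

test_that("undefined ATP/NADPH ratio is NA, not infinite", {
  mets <- rbind(metabolite("atp_c"), metabolite("adp_c"),
                metabolite("pi_c"), metabolite("h2o_c"),
                metabolite("h_c"), metabolite("nadph_c"),
                metabolite("nadh_c"))
  m <- metabolic_model(mets, list(
    reaction("SRC", c(atp_c = 1, adp_c = -1, pi_c = -1), lb = 0,
             gene_associated = FALSE),
    reaction("EX_adp", c(adp_c = 1), lb = 0, gene_associated = FALSE),
    reaction("EX_pi", c(pi_c = 1), lb = 0, gene_associated = FALSE),
    reaction("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1,
                       h_c = 1)),
    reaction("EX_h2o", c(h2o_c = 1), lb = 0, gene_associated = FALSE),
    reaction("EX_h", c(h_c = -1), gene_associated = FALSE)),
    objective = c(ATPM = 1))
  fs <- fba(m, "ATPM")
  cr <- cofactor_report(m, fs)
  expect_true(is.na(cr$atp_nadph_ratio))
})

test_that("yields compute productivity, mass yield and c-mol yield from formulas", {
  toy <- make_phototroph_toy()
  # pure production: all fixed carbon leaves as product, c-mol yield 1
  prodmax <- two_step_optimize(toy, "BIOMASS", "EX_prod_e",
                               biomass_fraction = 0)
  y <- yields(toy, prodmax, product_id = "prod_c",
              product_flux_id = "EX_prod_e",
              substrate_exchange_ids = "EX_co2_e",
              substrate_id = "co2_c")
  expect_equal(y$cmol_yield, 1, tolerance = 1e-6)
  expect_equal(y$productivity, phototroph_toy_constants()$p_max,
               tolerance = 1e-6)
  # mass yield from molar masses: C2H4 per 2 CO2
  expect_equal(y$mass_yield, 28.054 / (2 * 44.009), tolerance = 1e-4)
  # with growth in the mix, product carbon share drops below 1
  mixed <- two_step_optimize(toy, "BIOMASS", "EX_prod_e",
                             biomass_fraction = 0.1)
  ym <- yields(toy, mixed, "prod_c", "EX_prod_e", "EX_co2_e", "co2_c")
  expect_lt(ym$cmol_yield, 1)
  expect_gt(ym$cmol_yield, 0)
})

test_that("yields fail loudly with zero substrate uptake", {
  toy <- make_phototroph_toy()
  fs <- pfba(toy, "BIOMASS")
  expect_error(yields(toy, fs, "prod_c", "EX_prod_e", "EX_prod_e",
                      "co2_c"), "zero total substrate uptake")
})
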