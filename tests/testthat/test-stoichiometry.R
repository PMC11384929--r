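test_that("molar shares follow mass fraction / molar mass on both bases", {
  g <- molar_shares(glucose_composition(), basis = "ts")
  expect_equal(g[["C"]], 1 / 30, tolerance = 1e-12)
  expect_equal(g[["H"]], (12 / 180) / 1, tolerance = 1e-12)

  ino <- molar_shares(inoculum_composition(), basis = "vs")
  expect_equal(ino[["C"]], 0.3676 / 12 / 0.6044, tolerance = 1e-12)

  expect_error(molar_shares(
    elemental_composition(carbon_pct_ts = 0, hydrogen_pct_ts = 0)),
    "no carbon")
  z <- elemental_composition(carbon_pct_ts = 40, hydrogen_pct_ts = 7,
                             vs_pct_ts = 0)
  expect_error(molar_shares(z, basis = "vs"), "VS")
})

test_that("composition validation rejects impossible percentages", {
  expect_error(elemental_composition(carbon_pct_ts = 120,
                                     hydrogen_pct_ts = 5), "outside")
  expect_error(elemental_composition(carbon_pct_ts = 40, hydrogen_pct_ts = 7,
                                     vs_pct_ts = 80, ash_pct_ts = 30),
               "VS \\+ ash")
  expect_error(elemental_composition(carbon_pct_ts = 60, hydrogen_pct_ts = 20,
                                     oxygen_pct_ts = 30), "C\\+H\\+O\\+N\\+S")
})

test_that("Buswell balance reproduces textbook splits and flags over-oxidized input", {
  glu <- buswell_balance(c(C = 6, H = 12, O = 6))
  expect_equal(glu$water, 0)
  expect_equal(glu$ch4, 3)
  expect_equal(glu$co2, 3)
  expect_false(glu$flagged)

  # acetic acid as C2H4O2 splits evenly into CH4 + CO2
  ace <- buswell_balance(c(C = 2, H = 4, O = 2))
  expect_equal(ace$ch4, 1)
  expect_equal(ace$co2, 1)

  # carbonate-like C1O3 is over-oxidized: negative CH4, flagged not clamped
  expect_warning(ox <- buswell_balance(c(C = 1, O = 3)), "over-oxidized")
  expect_equal(ox$ch4, -0.25)
  expect_true(ox$flagged)

  expect_error(buswell_balance(c(C = 0, H = 4)), "carbon")
})

test_that("balance coefficients match the independent element-conservation solver", {
  set.seed(42)
  for (i in 1:25) {
    comp <- random_composition()
    sh <- molar_shares(comp, basis = "vs")
    bal <- suppressWarnings(buswell_balance(sh))
    orc <- oracle_buswell(sh[["C"]], sh[["H"]], sh[["O"]], sh[["N"]],
                          sh[["S"]])
    expect_equal(bal$water, orc$water, tolerance = 1e-10)
    expect_equal(bal$ch4, orc$ch4, tolerance = 1e-10)
    expect_equal(bal$co2, orc$co2, tolerance = 1e-10)
    # carbon conservation to machine precision
    expect_equal(bal$ch4 + bal$co2, sh[["C"]], tolerance = 1e-12)
  }
})

test_that("CHO-only compositions give identical results with and without N/S terms", {
  set.seed(7)
  for (i in 1:10) {
    comp <- elemental_composition(runif(1, 25, 50), runif(1, 3, 8),
                                  runif(1, 10, 40))
    sh <- molar_shares(comp)
    a <- buswell_balance(sh, include_ns = TRUE)
    b <- buswell_balance(sh, include_ns = FALSE)
    expect_identical(a[c("ch4", "co2", "water")], b[c("ch4", "co2", "water")])
  }
})

test_that("glucose potentials reach the stoichiometric biogas volume", {
  res <- ultimate_potentials(glucose_composition())
  expect_equal(res$biogas_ml_per_gvs, 6 / 180 * 22400, tolerance = 1e-12)
  expect_equal(res$biogas_ml_per_gvs, 746.6, tolerance = 1e-4)
  expect_equal(res$methane_fraction, 0.5, tolerance = 1e-12)
  expect_lte(res$ubmp_ml_per_gvs, res$biogas_ml_per_gvs)
  # scaling invariance: potentials are per-gram, so doubling the molar
  # volume is the only thing that changes the volume
  res2 <- ultimate_potentials(glucose_composition(), molar_volume_ml = 44800)
  expect_equal(res2$ubmp_ml_per_gvs, 2 * res$ubmp_ml_per_gvs)
})

test_that("per-gram potentials are invariant to formula scaling", {
  a <- ultimate_potentials(formula_composition(6, 12, 6))
  b <- ultimate_potentials(formula_composition(12, 24, 12))
  expect_equal(a$ubmp_ml_per_gvs, b$ubmp_ml_per_gvs, tolerance = 1e-12)
  expect_equal(a$biogas_ml_per_gvs, b$biogas_ml_per_gvs, tolerance = 1e-12)
})

test_that("ultimate yields scale by mass and mixtures add", {
  y <- ultimate_yield(377.9, 2.6)
  expect_gte(y$ubmy_ml, 982.5)
  expect_lte(y$ubmy_ml, 982.6)
  expect_equal(ultimate_yield(594.1, 5.2)$ubmy_ml, 3089.32, tolerance = 1e-6)
  expect_equal(ultimate_yield(500, 0)$ubmy_ml, 0)
  expect_error(ultimate_yield(500, -1), "nonnegative")

  expect_equal(mixture_ubmy(c(982.6, 3089.74)), 4072.34, tolerance = 1e-9)
  expect_equal(mixture_ubmy(list(y)), y$ubmy_ml)
  expect_equal(mixture_ubmy(c(5, 5, 5)), 15)
  # permutation invariance
  set.seed(1)
  v <- runif(5, 100, 1000)
  expect_equal(mixture_ubmy(v), mixture_ubmy(rev(v)))
  expect_error(mixture_ubmy(list()), "empty")
})
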