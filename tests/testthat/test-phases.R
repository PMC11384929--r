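make_series <- function(sigma = 0, seed = 1, interval_min = 15) {
  sp <- synthetic_spec(doses = 8, replicates = 1,
                       sample_interval_min = interval_min,
                       increment_noise_sigma_ml = sigma,
                       replicate_param_cv = 0)
  generate_experiment(sp, seed = seed)[[1]]
}

test_that("segmentation produces the half-open feed windows and re-zeroes", {
  s <- make_series()
  phases <- segment_phases(s, horizon = 60)
  expect_length(phases, 4)
  wins <- t(vapply(phases, attr, numeric(2), "window"))
  expect_equal(unname(wins[, 1]), c(0, 8, 21, 44))
  expect_equal(unname(wins[, 2]), c(8, 21, 44, 60))
  # phases whose feed instant is on the sampling grid start at zero; the
  # first phase's initial sample sits 15 min after feeding and already
  # carries that interval's production. Windows do not overlap.
  for (i in seq_along(phases)) {
    if (i > 1) expect_lt(abs(phases[[i]]$cumulative[1]), 1e-6)
    if (i < 4) expect_lt(max(phases[[i]]$times),
                         wins[i, 2] - wins[i, 1] + 1e-12)
  }

  # single feed: one window covering everything
  one <- s
  one$feed_events <- data.frame(day = 0, vs_fed_g = 2.6)
  ph1 <- segment_phases(one, horizon = 60)
  expect_length(ph1, 1)
  expect_equal(unname(attr(ph1[[1]], "window")), c(0, 60))

  bad <- s
  bad$feed_events <- data.frame(day = c(0, 70), vs_fed_g = 2.6)
  expect_error(segment_phases(bad, horizon = 60), "beyond")
})

test_that("segment volumes sum to the whole-series total", {
  for (seed in 1:3) {
    s <- make_series(sigma = 0.5, seed = seed)
    phases <- segment_phases(s, horizon = 60)
    finals <- vapply(phases, function(p) max(p$cumulative), numeric(1))
    total <- max(s$cumulative)
    # reader tolerance: a few sampling increments at the cut points
    expect_equal(sum(finals), total, tolerance = 1e-3)
  }
})

test_that("per-VS normalization is the stated linear scaling", {
  s <- make_series()
  ph <- segment_phases(s, horizon = 60)[[4]]
  n1 <- normalize_per_vs(ph, 2.6)
  expect_equal(n1$cumulative, ph$cumulative / 2.6)
  expect_equal(982.6 / 2.6, 377.9, tolerance = 1e-3)
  expect_equal(normalize_per_vs(ph, 1)$cumulative, ph$cumulative)
  expect_equal(normalize_per_vs(ph, 2)$cumulative * 2, ph$cumulative)
  expect_error(normalize_per_vs(ph, 0), "positive")
  # attribute-carried mass is used when present
  expect_equal(normalize_per_vs(ph)$cumulative, ph$cumulative / 2.6)
})

test_that("production rate converts increments to mL/hr", {
  t <- seq(0, 10, by = 1 / 24)
  lin <- gas_series(t, 24 * t)  # 24 mL/day
  r <- production_rate(lin, window_hr = 1)
  expect_true(all(abs(r$rate_ml_per_hr - 1) < 1e-9))

  flat <- gas_series(t, rep(5, length(t)))
  expect_true(all(production_rate(flat)$rate_ml_per_hr == 0))
  expect_error(production_rate(gas_series(1, 5)), "2 samples")

  # a Gompertz phase peaks at rmax/24 mL/hr (per-VS curve)
  p <- gompertz_params(394.16, 90.97, 0.10)
  tt <- seq(1 / 96, 14, by = 1 / 96)
  g <- gas_series(tt, gompertz_bmp(p, tt))
  rg <- production_rate(g, window_hr = 1)
  expect_equal(max(rg$rate_ml_per_hr), p$rmax / 24, tolerance = 0.02)
})

test_that("peak finding respects prominence, separation and boundaries", {
  # one hump
  t <- seq(0, 10, by = 0.01)
  hump <- dnorm(t, 5, 0.5) * 10
  pk <- find_peaks(t, hump, min_prominence = 0.5)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$day, 5, tolerance = 0.02)

  # two Gompertz pulses 10 days apart give two peaks
  p <- gompertz_params(300, 60, 0.3)
  tt <- seq(1 / 96, 20, by = 1 / 96)
  rate <- gompertz_rate(p, tt) + gompertz_rate(p, pmax(tt - 10, 0))
  pk2 <- find_peaks(tt, rate, min_prominence = 0.5, min_separation_days = 2)
  expect_identical(nrow(pk2), 2L)
  expect_equal(diff(pk2$day), 10, tolerance = 0.2)

  expect_identical(nrow(find_peaks(t, rep(0, length(t)))), 0L)
  # a monotone rate series has no interior maximum
  expect_identical(nrow(find_peaks(t, t^2)), 0L)
  expect_error(find_peaks(numeric(0), numeric(0)), "empty")
})

test_that("relative increase reproduces the printed dose comparisons", {
  expect_equal(relative_increase(334.71, 390.33), 14.25, tolerance = 1e-3)
  expect_equal(relative_increase(135.06, 390.33), 65.40, tolerance = 1e-3)
  expect_equal(relative_increase(7, 7), 0)
  expect_error(relative_increase(5, 0), "positive")

  m_bmp <- relative_increase_matrix(table_phase4_bmp, basis = "phase_bmp")
  expect_equal(m_bmp["4", "2"], 24.06, tolerance = 5e-3)
  expect_equal(m_bmp["8", "6"], 14.25, tolerance = 5e-3)
  m_bmy <- relative_increase_matrix(table_total_bmy, basis = "total_bmy")
  expect_equal(m_bmy["8", "6"], 3.24, tolerance = 5e-3)
  expect_equal(m_bmy["6", "2"], 8.87, tolerance = 5e-3)
  expect_true(all(diag(m_bmp) == 0))
  expect_true(all(is.na(m_bmp[upper.tri(m_bmp)])))

  expect_error(relative_increase_matrix(c(`2` = 10, `2` = 12)), "duplicate")
  expect_error(relative_increase_matrix(c(`2` = 10)), "at least 2")
})

test_that("relative increase is scale-invariant and algebraically consistent", {
  set.seed(12)
  for (i in 1:20) {
    a <- runif(1, 1, 500); b <- runif(1, 1, 500); c <- runif(1, 0.1, 10)
    expect_equal(relative_increase(a, b), relative_increase(c * a, c * b),
                 tolerance = 1e-12)
    expect_equal(relative_increase(a, b), 100 * (1 - a / b),
                 tolerance = 1e-12)
  }
})
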