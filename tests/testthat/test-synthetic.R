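test_that("the default design yields the full logging grid", {
  sp <- synthetic_spec()
  ex <- generate_experiment(sp, seed = 1)
  expect_length(ex, 15)  # 5 doses x 3 replicates
  expect_length(ex[[1]]$times, 5760)  # 60 d at 15 min
  expect_equal(max(ex[[1]]$times), 60)
})

test_that("zero noise and zero jitter reproduce the deterministic forward model", {
  sp <- synthetic_spec(doses = 8, replicates = 1,
                       increment_noise_sigma_ml = 0, replicate_param_cv = 0,
                       sample_interval_min = 60)
  ex <- generate_experiment(sp, seed = 99)
  s <- ex[[1]]
  p <- gompertz_params(394.16, 90.97, 0.10)
  det <- bmy_at(sp$inoculum, s$times)
  for (f in seq_along(sp$feed_days)) {
    tt <- pmax(s$times - sp$feed_days[f], 0)
    on <- tt > 0
    det[on] <- det[on] + gompertz_bmp(p, tt[on]) * 2.6
  }
  expect_equal(s$cumulative, det, tolerance = 1e-12)
})

test_that("generation is seed-deterministic and monotone", {
  sp <- synthetic_spec(doses = c(0, 8), replicates = 2,
                       sample_interval_min = 120)
  a <- generate_experiment(sp, seed = 42)
  b <- generate_experiment(sp, seed = 42)
  expect_identical(a, b)
  c_ <- generate_experiment(sp, seed = 43)
  expect_false(identical(a, c_))
  for (s in a) expect_true(all(diff(s$cumulative) >= 0))
})

test_that("ground truth matches the generated experiment and orders doses", {
  sp <- synthetic_spec(doses = c(8, 0, 4), replicates = 2,
                       sample_interval_min = 360,
                       replicate_param_cv = 0.05)
  gt <- ground_truth(sp, seed = 5)
  ex <- generate_experiment(sp, seed = 5)
  expect_identical(gt, attr(ex, "ground_truth"))
  doses <- vapply(gt, `[[`, numeric(1), "dose")
  expect_identical(unname(doses), rep(c(0, 4, 8), each = 2))
  # cv = 0 collapses replicates onto identical truth
  gt0 <- ground_truth(synthetic_spec(doses = 8, replicates = 3,
                                     sample_interval_min = 360,
                                     replicate_param_cv = 0), seed = 1)
  expect_identical(gt0[[1]]$params, gt0[[3]]$params)
})

test_that("final-phase per-VS yields increase with dose in expectation", {
  sp <- synthetic_spec(replicates = 1, sample_interval_min = 60,
                       increment_noise_sigma_ml = 0, replicate_param_cv = 0)
  ex <- generate_experiment(sp, seed = 2)
  finals <- vapply(ex, function(s) {
    ph <- segment_phases(s, horizon = 60)[[4]]
    max(ph$cumulative) / 2.6
  }, numeric(1))
  expect_true(all(diff(finals) > 0))  # doses sorted ascending
})

test_that("increment noise variance scales as sigma squared", {
  noise_var <- function(sig, seeds = 30) {
    mean(vapply(seq_len(seeds), function(s) {
      mk <- function(sg) generate_experiment(
        synthetic_spec(doses = 8, replicates = 1,
                       increment_noise_sigma_ml = sg,
                       replicate_param_cv = 0), seed = s)[[1]]
      s0 <- mk(0); sn <- mk(sig)
      act <- s0$times > 44.2 & s0$times < 45.5  # strong production window
      var(diff(sn$cumulative[act]) - diff(s0$cumulative[act]))
    }, numeric(1)))
  }
  v1 <- noise_var(0.5)
  v2 <- noise_var(1)
  expect_equal(v1, 0.5^2, tolerance = 0.2)
  expect_equal(v2 / v1, 4, tolerance = 0.25)
})

test_that("phase-4 fits recover the generating parameters", {
  # noiseless generated phase 4 (inoculum background removed) recovers truth
  sp <- synthetic_spec(doses = 8, replicates = 1,
                       increment_noise_sigma_ml = 0, replicate_param_cv = 0)
  ex <- generate_experiment(sp, seed = 1)
  s <- ex[[1]]
  s$cumulative <- cummax(pmax(s$cumulative - bmy_at(sp$inoculum, s$times), 0))
  ph <- segment_phases(s, horizon = 60)[[4]]
  fit <- fit_gompertz(ph$times, ph$cumulative / 2.6)
  truth <- ground_truth(sp, seed = 1)[[1]]$params
  expect_equal(fit$params$bbmp, truth$bbmp, tolerance = 1e-3)
  expect_equal(fit$params$rmax, truth$rmax, tolerance = 1e-2)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(replicates = 0), "replicate")
  expect_error(synthetic_spec(feed_days = c(1, 8)), "start at 0")
  expect_error(synthetic_spec(horizon_days = 40, feed_days = c(0, 44)),
               "cover")
  expect_error(synthetic_spec(doses = 3), "phase_params")
  expect_error(synthetic_spec(increment_noise_sigma_ml = -1), "nonnegative")
})

test_that("optional pH tracks follow the dose-dependent anchors", {
  sp <- synthetic_spec(doses = c(0, 8), replicates = 1,
                       sample_interval_min = 720, ph_tracks = TRUE)
  ex <- generate_experiment(sp, seed = 1)
  ph0 <- ex[["D0_R1"]]$ph
  ph8 <- ex[["D8_R1"]]$ph
  expect_lt(ph0$ph[ph0$day == 60], 4.5)   # acidified without additive
  expect_gt(ph8$ph[ph8$day == 60], 8)     # buffered at high dose
})
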