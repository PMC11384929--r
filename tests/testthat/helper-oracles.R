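# Independent stoichiometry oracle: solve the element-conservation linear
# system for the H2O / CH4 / CO2 coefficients instead of using closed-form
# expressions. Unknowns (w, m, d) with NH3 = n and H2S = s fixed:
#   C: m + d = c
#   H: h + 2w = 4m + 3n + 2s
#   O: o + w = 2d
oracle_buswell <- function(c_, h, o, n = 0, s = 0) {
  A <- rbind(c(0, 1, 1),
             c(2, -4, 0),
             c(1, 0, -2))
  b <- c(c_, 3 * n + 2 * s - h, -o)
  x <- solve(A, b)
  list(water = x[1], ch4 = x[2], co2 = x[3], nh3 = n, h2s = s)
}

# random plausible CHONS composition (mass % of TS)
random_composition <- function() {
  repeat {
    p <- c(C = runif(1, 20, 55), H = runif(1, 2, 9), O = runif(1, 5, 40),
           N = runif(1, 0, 5), S = runif(1, 0, 2))
    if (sum(p) <= 100) break
  }
  elemental_composition(p[["C"]], p[["H"]], p[["O"]], p[["N"]], p[["S"]],
                        vs_pct_ts = runif(1, 40, 99), ash_pct_ts = 0)
}

inoculum_composition <- function() {
  elemental_composition(carbon_pct_ts = 36.76, hydrogen_pct_ts = 5.00,
                        oxygen_pct_ts = 11.55, nitrogen_pct_ts = 5.28,
                        sulfur_pct_ts = 1.85, vs_pct_ts = 60.44,
                        ts_pct = 4.01, ash_pct_ts = 39.56,
                        label = "inoculum")
}

# single-feed pulse curve with plain (untruncated) increment noise, in mL on
# a vs_fed gram basis; the harness for estimator-recovery properties
noisy_pulse_curve <- function(params, sigma_ml, days = 14, vs_fed = 2.6,
                              step_days = 1 / 96) {
  tt <- seq(step_days, days, by = step_days)
  det <- gompertz_bmp(params, tt) * vs_fed
  if (sigma_ml > 0) det <- det + cumsum(rnorm(length(tt), 0, sigma_ml))
  list(times = tt, per_gvs = det / vs_fed)
}

# per-dose printed summary values used as dose-comparison inputs
table_phase4_bmp <- c(`0` = 135.06, `2` = 229.76, `4` = 302.56,
                      `6` = 334.71, `8` = 390.33)
table_total_bmy <- c(`0` = 1036.06, `2` = 2360.55, `4` = 2439.96,
                     `6` = 2590.20, `8` = 2676.92)
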