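#' First-order cumulative methane production model
#'
#' Single-pool first-order kinetics for residual inoculum carbon:
#' \deqn{BMY(t) = uBMY (1 - e^{-k t})}
#' with asymptotic yield \code{ubmy_ml} (mL CH4) and rate constant
#' \code{k_per_day} (1/d).
#'
#' @param ubmy_ml Ultimate yield asymptote, mL CH4; nonnegative.
#' @param k_per_day First-order rate constant, 1/day; positive.
#' @return Object of class \code{first_order_model}.
#' @examples
#' first_order_model(3089.74, 0.13)
#' @export
first_order_model <- function(ubmy_ml, k_per_day) {
  if (!is.finite(ubmy_ml) || ubmy_ml < 0) stop("ubmy_ml must be >= 0")
  if (!is.finite(k_per_day) || k_per_day <= 0) stop("k_per_day must be > 0")
  structure(list(ubmy_ml = ubmy_ml, k_per_day = k_per_day),
            class = "first_order_model")
}

#' @export
print.first_order_model <- function(x, ...) {
  cat(sprintf("First-order model: uBMY %.2f mL, k %.3f 1/d (t99 = %.1f d)\n",
              x$ubmy_ml, x$k_per_day, -log(0.01) / x$k_per_day))
  invisible(x)
}

#' Cumulative yield of a first-order model at time t
#'
#' @param model A [first_order_model()].
#' @param t Time in days, nonnegative; vectorized.
#' @return Cumulative methane volume in mL.
#' @examples
#' bmy_at(first_order_model(3089.74, 0.13), 36)
#' @export
bmy_at <- function(model, t) {
  stopifnot(inherits(model, "first_order_model"))
  if (any(t < 0)) stop("t must be nonnegative")
  model$ubmy_ml * (1 - exp(-model$k_per_day * t))
}

#' Fraction of the ultimate yield achieved by time t
#'
#' @param k First-order rate constant, 1/day; positive.
#' @param t Time in days, nonnegative; vectorized.
#' @return Fraction in [0, 1).
#' @examples
#' fraction_achieved(0.13, 36)  # 0.9907
#' @export
fraction_achieved <- function(k, t) {
  if (k <= 0) stop("k must be positive")
  if (any(t < 0)) stop("t must be nonnegative")
  1 - exp(-k * t)
}

#' Time to reach a target fraction of the ultimate yield
#'
#' Inverts the first-order curve: the real solution is \code{-log(1-target)/k};
#' the whole-day figure is its ceiling, so the reported day always meets or
#' exceeds the target fraction.
#'
#' @param k Rate constant, 1/day.
#' @param target Fraction in (0, 1).
#' @return List with \code{days} (real) and \code{whole_day} (integer).
#' @examples
#' time_to_fraction(0.13, 0.99)  # 35.42 d, whole day 36
#' @export
time_to_fraction <- function(k, target) {
  if (k <= 0) stop("k must be positive")
  if (target <= 0 || target >= 1) {
    stop("target must be in (0, 1); the asymptote is never reached")
  }
  d <- -log(1 - target) / k
  list(days = d, whole_day = as.integer(ceiling(d)))
}

#' Design a multi-feed assay plan that isolates the substrate-only phase
#'
#' Given a first-order model of the inoculum's residual carbon, marks the
#' day by which the target depletion fraction is reached (whole-day,
#' conservative) and identifies the first feed on or after that day as the
#' start of the isolated-substrate phase, in which the fed substrate is the
#' only carbon source. \code{settle_days} is the minimum residence required
#' for that final phase before the experiment horizon.
#'
#' @param inoculum A [first_order_model()] for the inoculum background.
#' @param target Depletion fraction to require, e.g. 0.99.
#' @param settle_days Minimum days the isolated phase must run.
#' @param horizon Total experiment length, days.
#' @param feed_days Feed event days; strictly increasing, first must be 0.
#' @param feed_masses_gvs g VS per feed; a scalar is recycled.
#' @param refeed_rate_threshold Production rate (mL CH4/hr) below which a
#'   reactor is considered ready for the next feed; metadata carried on the
#'   plan.
#' @return Object of class \code{feeding_plan} with fields \code{feed_days},
#'   \code{feed_masses_gvs}, \code{phase_windows} (data.frame start/end,
#'   half-open except the last), \code{depletion_day}, \code{settle_days},
#'   \code{isolated_phase_start}, \code{isolated_phase_index},
#'   \code{refeed_rate_threshold}, \code{horizon}.
#' @examples
#' design_plan(first_order_model(3089.74, 0.13), target = 0.99,
#'             settle_days = 14, horizon = 60, feed_days = c(0, 8, 21, 44))
#' @export
design_plan <- function(inoculum, target = 0.99, settle_days = 14,
                        horizon = 60, feed_days = c(0, 8, 21, 44),
                        feed_masses_gvs = 2.6,
                        refeed_rate_threshold = 0.1) {
  stopifnot(inherits(inoculum, "first_order_model"))
  if (length(feed_days) < 1 || feed_days[1] != 0) {
    stop("feed_days must start at day 0")
  }
  if (any(diff(feed_days) <= 0)) stop("feed_days must be strictly increasing")
  if (max(feed_days) >= horizon) stop("last feed is beyond the horizon")
  masses <- rep_len(feed_masses_gvs, length(feed_days))
  dep <- time_to_fraction(inoculum$k_per_day, target)
  if (horizon < dep$whole_day + settle_days) {
    stop(sprintf(
      "horizon %g too short: depletion day %d + settle %g requires >= %g days",
      horizon, dep$whole_day, settle_days, dep$whole_day + settle_days))
  }
  iso <- which(feed_days >= dep$whole_day)
  if (length(iso) == 0) {
    iso_idx <- NA_integer_
    iso_start <- NA_real_
  } else {
    iso_idx <- iso[1]
    iso_start <- feed_days[iso_idx]
    if (horizon < iso_start + settle_days) {
      stop(sprintf(
        "horizon %g too short: isolated phase at day %g needs %g settle days",
        horizon, iso_start, settle_days))
    }
  }
  windows <- data.frame(
    phase = seq_along(feed_days),
    start = feed_days,
    end = c(feed_days[-1], horizon))
  structure(
    list(feed_days = feed_days, feed_masses_gvs = masses,
         phase_windows = windows, depletion_day = dep$whole_day,
         depletion_day_real = dep$days, settle_days = settle_days,
         isolated_phase_start = iso_start, isolated_phase_index = iso_idx,
         refeed_rate_threshold = refeed_rate_threshold, horizon = horizon),
    class = "feeding_plan")
}

#' @export
print.feeding_plan <- function(x, ...) {
  cat("Feeding plan over", x$horizon, "days\n")
  cat("  feeds at day", paste(x$feed_days, collapse = ", "),
      "(", paste(signif(x$feed_masses_gvs, 4), collapse = ", "), "g VS )\n")
  cat(sprintf("  inoculum depletion day %d (%.2f d real)\n",
              x$depletion_day, x$depletion_day_real))
  if (!is.na(x$isolated_phase_index)) {
    cat(sprintf("  isolated-substrate phase %d: [%g, %g]\n",
                x$isolated_phase_index, x$isolated_phase_start, x$horizon))
  } else {
    cat("  no feed falls after the depletion day\n")
  }
  invisible(x)
}

#' First time the production rate stays below a re-feed threshold
#'
#' Scans a production-rate series for the earliest time after which the rate
#' remains below \code{threshold} for at least \code{persist_hr} hours (to
#' avoid triggering on noise dips). A below-threshold run that lasts to the
#' end of the series qualifies regardless of its length, since observation
#' simply ended while the reactor was quiet.
#'
#' @param times Days from experiment start, strictly increasing.
#' @param rates Production rates, mL CH4/hr.
#' @param threshold Re-feed threshold, mL CH4/hr (default 0.1).
#' @param persist_hr Persistence window in hours (default 2).
#' @return The earliest qualifying time (days), or \code{NA_real_} when the
#'   rate never settles below the threshold.
#' @export
refeed_ready <- function(times, rates, threshold = 0.1, persist_hr = 2) {
  if (length(rates) == 0) stop("empty rate series")
  if (length(times) != length(rates)) stop("times and rates lengths differ")
  below <- rates < threshold
  if (!any(below)) return(NA_real_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    dur_hr <- (times[ends[i]] - times[starts[i]]) * 24
    if (dur_hr >= persist_hr || ends[i] == length(rates)) {
      return(times[starts[i]])
    }
  }
  NA_real_
}
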