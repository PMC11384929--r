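#' One reactor's cumulative methane record
#'
#' Container for a cumulative CH4 time series as logged by an automatic
#' methane potential test system (normalized gas volume on a fixed sampling
#' grid), together with the reactor's additive dose, its feed events and an
#' optional pH track. Small cumulative dips (meter jitter) up to
#' \code{dip_tolerance} are clamped to monotone; larger violations are
#' rejected with the offending sample indices.
#'
#' @param times_days Days from experiment start; strictly increasing.
#' @param cumulative_ml Cumulative CH4 volume, mL; nondecreasing within
#'   tolerance.
#' @param reactor_id Reactor identifier.
#' @param dose_g_per_l Additive (biochar) dose, g per litre of reactor
#'   volume; nonnegative.
#' @param feed_events data.frame with columns \code{day} and \code{vs_fed_g}.
#' @param ph Optional data.frame with columns \code{day} and \code{ph}.
#' @param dip_tolerance Maximum cumulative dip (mL) clamped silently.
#' @return Object of class \code{gas_series}.
#' @export
gas_series <- function(times_days, cumulative_ml, reactor_id = "R1",
                       dose_g_per_l = 0, feed_events = NULL, ph = NULL,
                       dip_tolerance = 0.01) {
  n <- length(times_days)
  if (n < 1 || length(cumulative_ml) != n) {
    stop("times and cumulative volumes must be nonempty and equal length")
  }
  if (any(diff(times_days) <= 0)) {
    bad <- which(diff(times_days) <= 0)[1] + 1
    stop("times not strictly increasing at sample ", bad)
  }
  if (dose_g_per_l < 0) stop("dose must be nonnegative")
  run_max <- cummax(cumulative_ml)
  dip <- run_max - cumulative_ml
  if (any(dip > dip_tolerance)) {
    bad <- which(dip > dip_tolerance)
    stop("cumulative volume decreases beyond tolerance at sample(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(feed_events)) {
    stopifnot(all(c("day", "vs_fed_g") %in% names(feed_events)))
    feed_events <- feed_events[order(feed_events$day), , drop = FALSE]
  }
  structure(
    list(times = as.numeric(times_days), cumulative = run_max,
         reactor_id = as.character(reactor_id),
         dose_g_per_l = dose_g_per_l, feed_events = feed_events, ph = ph,
         units = "mL"),
    class = "gas_series")
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("Gas series '%s': %d samples over %.2f d, final %.2f %s",
              x$reactor_id, length(x$times), max(x$times),
              x$cumulative[length(x$cumulative)], x$units))
  cat(sprintf(", dose %g g/L", x$dose_g_per_l))
  if (!is.null(x$feed_events)) {
    cat(sprintf(", %d feeds", nrow(x$feed_events)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.gas_series <- function(x, ...) {
  plot(x$times, x$cumulative, type = "l", xlab = "time (days)",
       ylab = paste0("cumulative CH4 (", x$units, ")"),
       main = x$reactor_id, ...)
  if (!is.null(x$feed_events)) {
    graphics::abline(v = x$feed_events$day, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Segment a cumulative series into feeding phases
#'
#' Splits a reactor record at its feed events into half-open windows
#' \code{[feed_i, feed_{i+1})}, the last window closed at \code{horizon}.
#' Each phase's cumulative volume is re-zeroed to the (linearly interpolated)
#' value at its feed instant, so a phase starts at zero and its final value
#' is the volume produced within that phase.
#'
#' @param series A [gas_series()] with nonempty \code{feed_events}, first
#'   feed at day 0.
#' @param horizon End of the experiment in days; defaults to the last sample.
#' @return List of per-phase \code{gas_series}, each carrying attributes
#'   \code{window} (c(start, end)), \code{phase_index} and \code{vs_fed_g}.
#' @export
segment_phases <- function(series, horizon = NULL) {
  stopifnot(inherits(series, "gas_series"))
  fe <- series$feed_events
  if (is.null(fe) || nrow(fe) == 0) stop("series has no feed events")
  if (fe$day[1] != 0) stop("first feed must be at day 0")
  if (is.null(horizon)) horizon <- max(series$times)
  if (any(fe$day >= horizon)) stop("feed event at or beyond the horizon")
  starts <- fe$day
  ends <- c(fe$day[-1], horizon)
  lapply(seq_along(starts), function(i) {
    in_win <- if (i == length(starts)) {
      series$times >= starts[i] & series$times <= ends[i]
    } else {
      series$times >= starts[i] & series$times < ends[i]
    }
    if (!any(in_win)) stop("phase ", i, " window contains no samples")
    zero <- interp_cumulative(series, starts[i])
    ph <- gas_series(series$times[in_win] - starts[i],
                     pmax(series$cumulative[in_win] - zero, 0),
                     reactor_id = series$reactor_id,
                     dose_g_per_l = series$dose_g_per_l)
    attr(ph, "window") <- c(start = starts[i], end = ends[i])
    attr(ph, "phase_index") <- i
    attr(ph, "vs_fed_g") <- fe$vs_fed_g[i]
    ph
  })
}

# cumulative value at an arbitrary day; constant extrapolation at the edges,
# zero before the first sample when the series starts after day 0
interp_cumulative <- function(series, day) {
  if (day <= series$times[1]) {
    if (series$times[1] <= 0) return(series$cumulative[1]) else return(0)
  }
  stats::approx(series$times, series$cumulative, xout = day, rule = 2)$y
}

#' Normalize a phase curve per gram of volatile solids fed
#'
#' @param phase A [gas_series()] (typically from [segment_phases()]).
#' @param vs_fed Grams of VS fed in this phase; positive. Defaults to the
#'   phase's \code{vs_fed_g} attribute when present.
#' @return A \code{gas_series} in mL/g-VS (units field updated).
#' @export
normalize_per_vs <- function(phase, vs_fed = NULL) {
  stopifnot(inherits(phase, "gas_series"))
  if (is.null(vs_fed)) vs_fed <- attr(phase, "vs_fed_g")
  if (is.null(vs_fed) || !is.finite(vs_fed) || vs_fed <= 0) {
    stop("vs_fed must be a positive mass in grams")
  }
  out <- phase
  out$cumulative <- phase$cumulative / vs_fed
  out$units <- "mL/g-VS"
  out
}

#' Methane production rate from a cumulative series
#'
#' Finite differences of the cumulative volume converted to mL/hr, smoothed
#' with a centered moving average spanning \code{window_hr} hours (edge
#' windows shrink rather than dropping samples). Rates are reported at the
#' increment midpoints.
#'
#' @param series A [gas_series()].
#' @param window_hr Smoothing window in hours (default 1).
#' @return data.frame with \code{time_days} and \code{rate_ml_per_hr}.
#' @export
production_rate <- function(series, window_hr = 1) {
  stopifnot(inherits(series, "gas_series"))
  if (length(series$times) < 2) stop("need at least 2 samples")
  dt_hr <- diff(series$times) * 24
  rate <- diff(series$cumulative) / dt_hr
  mid <- (series$times[-1] + series$times[-length(series$times)]) / 2
  step_hr <- stats::median(dt_hr)
  w <- max(1, round(window_hr / step_hr))
  if (w > 1) {
    rate <- zoo::rollapply(rate, width = w, FUN = mean, partial = TRUE,
                           align = "center")
  }
  data.frame(time_days = mid, rate_ml_per_hr = as.numeric(rate))
}

#' Locate production-rate peaks
#'
#' Finds interior local maxima of a rate series with at least
#' \code{min_prominence} topographic prominence (height above the higher of
#' the two valley floors separating the peak from taller terrain or the
#' series edge), then enforces a minimum separation, keeping the taller peak
#' of any conflicting pair. Boundary samples are never peaks.
#'
#' @param times Days; strictly increasing.
#' @param rates Rates, mL/hr.
#' @param min_prominence Minimum prominence, mL/hr (default 0.5).
#' @param min_separation_days Minimum spacing between reported peaks.
#' @return data.frame with \code{day}, \code{rate_ml_per_hr}; zero rows when
#'   nothing qualifies.
#' @export
find_peaks <- function(times, rates, min_prominence = 0.5,
                       min_separation_days = 0.5) {
  if (length(rates) == 0) stop("empty rate series")
  n <- length(rates)
  empty <- data.frame(day = numeric(0), rate_ml_per_hr = numeric(0))
  if (n < 3) return(empty)
  cand <- which(rates[2:(n - 1)] > rates[1:(n - 2)] &
                rates[2:(n - 1)] >= rates[3:n]) + 1
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) {
    h <- rates[i]
    left <- if (i > 1) rates[1:(i - 1)] else numeric(0)
    right <- if (i < n) rates[(i + 1):n] else numeric(0)
    base_side <- function(v) {
      higher <- which(v >= h)
      if (length(higher) == 0) min(v) else {
        # valley floor between the peak and the nearest taller sample
        min(v[seq_len(max(higher))])
      }
    }
    lb <- if (length(left)) base_side(rev(left)) else h
    rb <- if (length(right)) base_side(right) else h
    h - max(lb, rb)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0) return(empty)
  keep <- keep[order(rates[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) {
    if (all(abs(times[i] - times[sel]) >= min_separation_days)) {
      sel <- c(sel, i)
    }
  }
  sel <- sort(sel)
  data.frame(day = times[sel], rate_ml_per_hr = rates[sel])
}

#' Relative increase between a lower- and a higher-dose result
#'
#' The dose-comparison statistic
#' \deqn{RI = 100 (high - low) / high = 100 (1 - low/high)}
#' expressed in percent, with the higher-dose value as denominator.
#'
#' @param low_value Result at the lower dose (mL or mL/g-VS).
#' @param high_value Result at the higher dose, same units; must be positive.
#' @return Relative increase in percent.
#' @examples
#' relative_increase(334.71, 390.33)  # 14.25
#' @export
relative_increase <- function(low_value, high_value) {
  if (any(high_value <= 0)) stop("high_value must be positive")
  (high_value - low_value) / high_value * 100
}

#' Pairwise relative-increase matrix across doses
#'
#' Computes [relative_increase()] for every ordered dose pair (higher vs
#' lower), arranged as a lower-triangular matrix with rows = higher dose,
#' columns = lower dose, and zeros on the diagonal.
#'
#' @param values Named numeric vector of per-dose results; names are doses in
#'   g/L (coercible to numeric) and must be unique.
#' @param basis Which quantity the values are: \code{"phase_bmp"} (per-phase
#'   BMP, mL/g-VS) or \code{"total_bmy"} (whole-experiment BMY, mL).
#' @return Matrix of class \code{ri_matrix} (percent), doses ascending, with
#'   attribute \code{basis}.
#' @examples
#' relative_increase_matrix(
#'   c(`0` = 135.06, `2` = 229.76, `4` = 302.56, `6` = 334.71, `8` = 390.33),
#'   basis = "phase_bmp")
#' @export
relative_increase_matrix <- function(values,
                                     basis = c("phase_bmp", "total_bmy")) {
  basis <- match.arg(basis)
  if (length(values) < 2) stop("need at least 2 doses")
  doses <- suppressWarnings(as.numeric(names(values)))
  if (any(is.na(doses))) stop("values must be named by numeric dose")
  if (anyDuplicated(doses)) stop("duplicate dose labels")
  ord <- order(doses)
  doses <- doses[ord]; values <- values[ord]
  k <- length(doses)
  m <- matrix(NA_real_, k, k, dimnames = list(doses, doses))
  diag(m) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i > j) m[i, j] <- relative_increase(values[j], values[i])
    }
  }
  structure(m, class = c("ri_matrix", "matrix"), basis = basis)
}

#' @export
print.ri_matrix <- function(x, ...) {
  cat("Relative increase (%), basis:", attr(x, "basis"),
      "- rows: higher dose, cols: lower dose\n")
  print(round(unclass(x), 2), na.print = "")
  invisible(x)
}
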