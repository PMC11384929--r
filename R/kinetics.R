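#' Modified-Gompertz parameter set
#'
#' The three-parameter sigmoid used for cumulative methane potential curves:
#' \deqn{BMP(t) = bBMP \exp\{-\exp[\frac{R_{max} e}{bBMP}(\lambda - t) + 1]\}}
#' with plateau \code{bbmp} (mL CH4/g-VS), maximum production rate \code{rmax}
#' (mL CH4/g-VS/day) and lag phase \code{lag_days} (days). \code{e} is the
#' exact Euler constant exp(1).
#'
#' @param bbmp Plateau, mL CH4/g-VS; positive.
#' @param rmax Maximum rate, mL CH4/g-VS/day; positive.
#' @param lag_days Lag phase, days; nonnegative.
#' @return Object of class \code{gompertz_params}.
#' @examples
#' gompertz_params(394.16, 90.97, 0.10)
#' @export
gompertz_params <- function(bbmp, rmax, lag_days) {
  if (!is.finite(bbmp) || bbmp <= 0) stop("bbmp must be positive")
  if (!is.finite(rmax) || rmax <= 0) stop("rmax must be positive")
  if (!is.finite(lag_days) || lag_days < 0) stop("lag_days must be >= 0")
  structure(list(bbmp = bbmp, rmax = rmax, lag_days = lag_days),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Modified Gompertz: bBMP %.2f mL/g-VS, Rmax %.2f mL/g-VS/d, lag %.2f d\n",
    x$bbmp, x$rmax, x$lag_days))
  invisible(x)
}

#' Evaluate the modified-Gompertz cumulative curve
#'
#' @param params A [gompertz_params()].
#' @param t Days, nonnegative; vectorized.
#' @return Cumulative methane potential, mL CH4/g-VS.
#' @examples
#' gompertz_bmp(gompertz_params(394.16, 90.97, 0.10), c(0, 1, 5, 14))
#' @export
gompertz_bmp <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  a <- params$rmax * exp(1) / params$bbmp
  params$bbmp * exp(-exp(a * (params$lag_days - t) + 1))
}

#' Instantaneous modified-Gompertz production rate
#'
#' Analytic time-derivative of [gompertz_bmp()]; its maximum over t equals
#' \code{rmax} (attained where the inner exponent crosses zero).
#'
#' @inheritParams gompertz_bmp
#' @return Production rate, mL CH4/g-VS/day.
#' @export
gompertz_rate <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  a <- params$rmax * exp(1) / params$bbmp
  u <- a * (params$lag_days - t) + 1
  params$bbmp * a * exp(u - exp(u))
}

#' Goodness-of-fit diagnostics for a fitted curve
#'
#' RMSE = sqrt(RSS/n); R2 = 1 - RSS/TSS with TSS about the observed mean;
#' the Nash-Sutcliffe model efficiency (NSE) uses the identical formula and is
#' reported alongside; AIC uses the Gaussian-likelihood form
#' n log(RSS/n) + 2(K+1) with K estimated parameters (the residual variance
#' counts as a parameter). With a zero-variance observed series R2 and NSE are
#' undefined and returned as NA with \code{undefined_r2 = TRUE}.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 2.
#' @param n_params Number of fitted model parameters K.
#' @param converged Convergence flag to carry on the result.
#' @return Object of class \code{fit_diagnostics}: \code{rmse},
#'   \code{r_squared}, \code{nse}, \code{aic}, \code{n_points},
#'   \code{residual_sum_squares}, \code{converged}, \code{undefined_r2}.
#' @examples
#' fit_diagnostics(c(1, 2, 3), c(1, 2, 4), n_params = 1)
#' @export
fit_diagnostics <- function(observed, predicted, n_params,
                            converged = TRUE) {
  n <- length(observed)
  if (n < 2 || length(predicted) != n) {
    stop("observed and predicted must have equal length >= 2")
  }
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  undef <- tss <= 0
  r2 <- if (undef) NA_real_ else 1 - rss / tss
  aic <- n * log(rss / n) + 2 * (n_params + 1)
  structure(
    list(rmse = sqrt(rss / n), r_squared = r2, nse = r2, aic = aic,
         n_points = n, residual_sum_squares = rss, converged = converged,
         undefined_r2 = undef),
    class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("Fit over %d points: RMSE %.4g, R2 %s, AIC %.4g%s\n",
              x$n_points, x$rmse,
              if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared),
              x$aic, if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

# Starting values: plateau from the curve maximum, rate from the steepest
# smoothed finite difference, lag from the first time 1% of the maximum is
# reached.
gompertz_start <- function(times, values) {
  vmax <- max(values)
  dv <- diff(values) / diff(times)
  if (length(dv) >= 5) {
    dv <- stats::filter(dv, rep(1 / 5, 5), sides = 2)
    dv <- dv[!is.na(dv)]
  }
  rmax0 <- max(dv, 1e-6)
  lag0 <- times[which(values >= 0.01 * vmax)[1]]
  list(bbmp = vmax, rmax = rmax0, lag_days = max(lag0, 0))
}

#' Fit the modified-Gompertz model to a cumulative per-g-VS curve
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) with all
#' parameters bounded below at zero. Starting values come from a data-driven
#' heuristic unless \code{init} is given. Non-convergence is reported on the
#' diagnostics of the best iterate, never silently.
#'
#' @param times Days, nonnegative, strictly increasing, length >= 8.
#' @param values Cumulative methane potential, mL CH4/g-VS.
#' @param init Optional [gompertz_params()] starting point.
#' @return List of class \code{gompertz_fit} with \code{params}
#'   ([gompertz_params()]) and \code{diagnostics} ([fit_diagnostics()]).
#' @examples
#' p <- gompertz_params(394.16, 90.97, 0.10)
#' t <- seq(0, 14, by = 1 / 96)
#' fit_gompertz(t, gompertz_bmp(p, t))
#' @export
fit_gompertz <- function(times, values, init = NULL) {
  check_fit_series(times, values)
  if (all(values == 0)) stop("degenerate series: all values are zero")
  st <- if (is.null(init)) gompertz_start(times, values)
        else list(bbmp = init$bbmp, rmax = init$rmax, lag_days = init$lag_days)
  dat <- data.frame(t = times, y = values)
  fit <- minpack.lm::nlsLM(
    y ~ bbmp * exp(-exp(rmax * exp(1) / bbmp * (lag_days - t) + 1)),
    data = dat, start = st,
    lower = c(bbmp = 1e-8, rmax = 1e-8, lag_days = 0),
    control = minpack.lm::nls.lm.control(
      maxiter = 1024, maxfev = 10000, ftol = 1e-10, ptol = 1e-10))
  cf <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  params <- gompertz_params(cf[["bbmp"]], cf[["rmax"]], cf[["lag_days"]])
  diag <- fit_diagnostics(values, stats::fitted(fit), n_params = 3,
                          converged = converged)
  structure(list(params = params, diagnostics = diag, model = fit),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  print(x$params); print(x$diagnostics); invisible(x)
}

#' Fit the first-order model to a cumulative per-g-VS curve
#'
#' Least-squares estimate of \code{ubmy (1 - exp(-k t))}; the starting rate
#' constant comes from the early-time slope (which approximates
#' \code{ubmy * k}).
#'
#' @inheritParams fit_gompertz
#' @return List of class \code{first_order_fit} with \code{params}
#'   ([first_order_model()]) and \code{diagnostics}.
#' @export
fit_first_order <- function(times, values) {
  check_fit_series(times, values)
  if (all(values == 0)) stop("degenerate series: all values are zero")
  vmax <- max(values)
  early <- which(values <= 0.5 * vmax)
  slope <- if (length(early) >= 2) {
    stats::coef(stats::lm(values[early] ~ times[early]))[2]
  } else vmax * 0.1
  k0 <- max(as.numeric(slope) / vmax, 1e-3)
  dat <- data.frame(t = times, y = values)
  fit <- minpack.lm::nlsLM(
    y ~ ubmy * (1 - exp(-k * t)), data = dat,
    start = list(ubmy = vmax, k = k0),
    lower = c(ubmy = 1e-8, k = 1e-8),
    control = minpack.lm::nls.lm.control(
      maxiter = 1024, maxfev = 10000, ftol = 1e-10, ptol = 1e-10))
  cf <- stats::coef(fit)
  params <- first_order_model(cf[["ubmy"]], cf[["k"]])
  diag <- fit_diagnostics(values, stats::fitted(fit), n_params = 2,
                          converged = isTRUE(fit$convInfo$isConv))
  structure(list(params = params, diagnostics = diag, model = fit),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  print(x$params); print(x$diagnostics); invisible(x)
}

check_fit_series <- function(times, values) {
  if (length(times) < 8) stop("need at least 8 time points")
  if (length(values) != length(times)) stop("times/values length mismatch")
  if (any(times < 0)) stop("times must be nonnegative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  invisible(TRUE)
}
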