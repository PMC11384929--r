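#' Chronological 70/20/10 split of a series
#'
#' Splits a series into contiguous training, validation and prediction
#' segments in time order. Segment lengths are \code{floor(f * n)} for the
#' validation and prediction fractions, with the remainder assigned to
#' training, so the three segments always concatenate back to the input.
#'
#' @param x Numeric series, length >= 10.
#' @param fractions Train/validation/prediction fractions summing to 1.
#' @return List with \code{train}, \code{validation}, \code{prediction} and
#'   an index list \code{idx} of the same names.
#' @examples
#' lengths(chronological_split(seq_len(5760))[1:3])  # 4032 1152 576
#' @export
chronological_split <- function(x, fractions = c(0.7, 0.2, 0.1)) {
  n <- length(x)
  if (n < 10) stop("series too short to split (need >= 10 points)")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n_val <- floor(fractions[2] * n)
  n_pred <- floor(fractions[3] * n)
  n_train <- n - n_val - n_pred
  idx <- list(train = seq_len(n_train),
              validation = seq_len(n_val) + n_train,
              prediction = seq_len(n_pred) + n_train + n_val)
  list(train = x[idx$train], validation = x[idx$validation],
       prediction = x[idx$prediction], idx = idx)
}

#' Fit a single ARIMA(p,d,q) candidate
#'
#' Thin wrapper around [stats::arima()] (Gaussian maximum likelihood after
#' conditional-sum-of-squares initialization). A mean is included when
#' \code{d = 0}; a linear drift can be requested via a regression term for
#' differenced models. Non-stationary, non-invertible or otherwise failing
#' fits are returned flagged (\code{ok = FALSE}) rather than raised, so grid
#' searches can continue.
#'
#' @param x Numeric series.
#' @param order Integer vector \code{c(p, d, q)}.
#' @param drift Include a linear drift regressor.
#' @return List of class \code{arima_fit}: \code{ok}, \code{order},
#'   \code{drift}, \code{model}, \code{aic}, \code{diagnostics} (in-sample,
#'   via [fit_diagnostics()]), \code{message}.
#' @export
fit_order <- function(x, order, drift = FALSE) {
  p <- order[1]; d <- order[2]; q <- order[3]
  if (any(order < 0)) stop("orders must be nonnegative")
  if (length(x) <= p + q + d + 2) {
    stop("series too short for order (", paste(order, collapse = ","), ")")
  }
  xreg <- if (drift) matrix(seq_along(x), dimnames = list(NULL, "drift"))
          else NULL
  warns <- character(0)
  res <- withCallingHandlers(
    tryCatch({
      m <- stats::arima(x, order = c(p, d, q), xreg = xreg,
                        include.mean = (d == 0), method = "CSS-ML")
      pred <- as.numeric(x - stats::residuals(m))
      diag <- fit_diagnostics(as.numeric(x), pred, n_params = length(m$coef))
      list(ok = TRUE, model = m, aic = m$aic, diagnostics = diag,
           message = NA_character_)
    }, error = function(e) {
      list(ok = FALSE, model = NULL, aic = NA_real_, diagnostics = NULL,
           message = conditionMessage(e))
    }),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  structure(c(list(order = c(p = p, d = d, q = q), drift = drift), res,
              list(warnings = unique(warns))),
            class = "arima_fit")
}

#' @export
print.arima_fit <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d)%s: ", x$order[1], x$order[2], x$order[3],
              if (x$drift) "+drift" else ""))
  if (x$ok) cat(sprintf("AIC %.2f, in-sample RMSE %.4g\n",
                        x$aic, x$diagnostics$rmse))
  else cat("failed:", x$message, "\n")
  invisible(x)
}

#' One-step-ahead forecast metrics on a held-out segment
#'
#' Applies a fitted candidate's coefficients, without re-estimation, to the
#' concatenation of its history and a new segment (Kalman filtering via
#' [stats::arima()] with all coefficients fixed), and scores the one-step-
#' ahead predictions over the segment with the standard diagnostics.
#'
#' @param fit An \code{ok} [fit_order()] result.
#' @param segment Numeric held-out segment; nonempty.
#' @param history The series the model was fitted on (and anything between
#'   it and \code{segment}), in time order.
#' @return [fit_diagnostics()] over the segment.
#' @export
forecast_metrics <- function(fit, segment, history) {
  stopifnot(inherits(fit, "arima_fit"))
  if (!fit$ok) stop("cannot score a failed fit")
  if (length(segment) == 0) stop("empty segment")
  full <- c(history, segment)
  xreg <- if (fit$drift) matrix(seq_along(full),
                                dimnames = list(NULL, "drift")) else NULL
  cf <- stats::coef(fit$model)
  refit <- suppressWarnings(
    stats::arima(full, order = unname(fit$order), xreg = xreg,
                 include.mean = (fit$order[["d"]] == 0),
                 fixed = cf, transform.pars = FALSE))
  pred <- as.numeric(full - stats::residuals(refit))
  seg_idx <- length(history) + seq_along(segment)
  fit_diagnostics(as.numeric(segment), pred[seg_idx],
                  n_params = length(cf))
}

#' Select an ARIMA order by training-segment AIC over a bounded grid
#'
#' Splits the series chronologically ([chronological_split()]), fits every
#' (p, d, q) candidate in the grid on the training segment, selects the
#' minimum-AIC candidate (ties broken by smaller p+q, then smaller d), and
#' scores the winner on all three segments with one-step-ahead diagnostics.
#'
#' @param x Numeric series.
#' @param p_max,q_max,d_max Grid bounds (defaults 8, 8, 2).
#' @param fractions Split fractions, see [chronological_split()].
#' @param drift Include a drift regressor in differenced candidates.
#' @return Object of class \code{arima_report}: \code{order},
#'   \code{selected_by} ("aic"), \code{fit} (the winning [fit_order()]),
#'   \code{diagnostics} (list train/validation/prediction),
#'   \code{n_train}/\code{n_val}/\code{n_test}, \code{candidates}
#'   (data.frame p, d, q, aic, ok), \code{degenerate}.
#' @export
select_order <- function(x, p_max = 8, q_max = 8, d_max = 2,
                         fractions = c(0.7, 0.2, 0.1), drift = FALSE) {
  if (p_max < 0 || q_max < 0 || d_max < 0) stop("invalid grid bounds")
  sp <- chronological_split(x, fractions)
  train <- sp$train
  degenerate <- stats::var(train) == 0
  grid <- expand.grid(p = 0:p_max, d = 0:d_max, q = 0:q_max)
  fits <- vector("list", nrow(grid))
  aics <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ord <- c(grid$p[i], grid$d[i], grid$q[i])
    if (length(train) <= sum(ord) + 2) next
    fits[[i]] <- fit_order(train, ord, drift = drift && ord[2] > 0)
    if (fits[[i]]$ok) aics[i] <- fits[[i]]$aic
  }
  if (all(is.na(aics))) {
    msgs <- unique(stats::na.omit(vapply(
      fits, function(f) if (is.null(f)) NA_character_ else f$message,
      character(1))))
    stop("all candidate fits failed: ", paste(msgs, collapse = "; "))
  }
  # minimum AIC; ties by smaller p+q, then smaller d
  key <- order(aics, grid$p + grid$q, grid$d, na.last = TRUE)
  best_i <- key[1]
  best <- fits[[best_i]]
  diag <- list(
    train = best$diagnostics,
    validation = forecast_metrics(best, sp$validation, history = train),
    prediction = forecast_metrics(best, sp$prediction,
                                  history = c(train, sp$validation)))
  structure(
    list(order = best$order, selected_by = "aic", fit = best,
         diagnostics = diag,
         n_train = length(train), n_val = length(sp$validation),
         n_test = length(sp$prediction),
         candidates = data.frame(grid, aic = aics,
                                 ok = vapply(fits, function(f)
                                   !is.null(f) && f$ok, logical(1))),
         degenerate = degenerate),
    class = "arima_report")
}

#' @export
print.arima_report <- function(x, ...) {
  cat(sprintf("Selected ARIMA(%d,%d,%d) by %s over %d candidates%s\n",
              x$order[1], x$order[2], x$order[3], x$selected_by,
              nrow(x$candidates),
              if (x$degenerate) " [degenerate series]" else ""))
  cat(sprintf("  split %d/%d/%d; train AIC %.2f\n",
              x$n_train, x$n_val, x$n_test, x$fit$aic))
  for (seg in c("validation", "prediction")) {
    d <- x$diagnostics[[seg]]
    cat(sprintf("  %s: RMSE %.4g, R2 %s\n", seg, d$rmse,
                if (is.na(d$r_squared)) "undefined"
                else sprintf("%.4f", d$r_squared)))
  }
  invisible(x)
}
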