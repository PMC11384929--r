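#' Write an experiment to the standard CSV pair
#'
#' Writes the long-format series table (\code{time_days, reactor_id,
#' cumulative_ml}) and a sidecar design table (\code{reactor_id,
#' dose_g_per_l, feed_day, vs_fed_g}, one row per feed event).
#'
#' @param experiment A \code{bmp_experiment} or list of [gas_series()].
#' @param series_path Path of the series CSV.
#' @param config_path Path of the sidecar CSV; default replaces the series
#'   file extension with \code{_design.csv}.
#' @return Invisibly, the two paths.
#' @export
write_gas_series <- function(experiment, series_path,
                             config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- sub("\\.csv$", "_design.csv", series_path)
  }
  rows <- lapply(experiment, function(s) {
    data.frame(time_days = s$times, reactor_id = s$reactor_id,
               cumulative_ml = s$cumulative)
  })
  utils::write.csv(do.call(rbind, rows), series_path, row.names = FALSE)
  cfg <- lapply(experiment, function(s) {
    fe <- s$feed_events
    if (is.null(fe)) fe <- data.frame(day = 0, vs_fed_g = NA_real_)
    data.frame(reactor_id = s$reactor_id, dose_g_per_l = s$dose_g_per_l,
               feed_day = fe$day, vs_fed_g = fe$vs_fed_g)
  })
  utils::write.csv(do.call(rbind, cfg), config_path, row.names = FALSE)
  invisible(c(series = series_path, config = config_path))
}

#' Read gas series from the standard CSV pair
#'
#' Validates as it reads: required columns must be present; per-reactor times
#' must be strictly increasing with no duplicate (reactor, time) rows (the
#' first offending row number is named in the error); cumulative dips within
#' \code{dip_tolerance} are clamped to monotone with a message, larger ones
#' are rejected.
#'
#' @param series_path CSV with columns \code{time_days, reactor_id,
#'   cumulative_ml}.
#' @param config_path Optional sidecar CSV (\code{reactor_id, dose_g_per_l,
#'   feed_day, vs_fed_g}).
#' @param dip_tolerance Maximum clamped cumulative dip, mL (default 0.01).
#' @return Named list of [gas_series()].
#' @export
read_gas_series <- function(series_path, config_path = NULL,
                            dip_tolerance = 0.01) {
  df <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  need <- c("time_days", "reactor_id", "cumulative_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cfg <- NULL
  if (!is.null(config_path)) {
    cfg <- utils::read.csv(config_path, stringsAsFactors = FALSE)
    cneed <- c("reactor_id", "dose_g_per_l", "feed_day", "vs_fed_g")
    cmiss <- setdiff(cneed, names(cfg))
    if (length(cmiss)) {
      stop("design table missing column(s): ", paste(cmiss, collapse = ", "))
    }
  }
  df$.row <- seq_len(nrow(df))
  out <- list()
  for (id in unique(df$reactor_id)) {
    sub <- df[df$reactor_id == id, ]
    dup <- duplicated(sub$time_days)
    if (any(dup)) {
      stop("duplicate (reactor, time) at row ", sub$.row[which(dup)[1]],
           " for reactor ", id)
    }
    if (any(diff(sub$time_days) < 0)) {
      bad <- which(diff(sub$time_days) < 0)[1] + 1
      stop("unsorted times for reactor ", id, " at row ", sub$.row[bad])
    }
    cum <- sub$cumulative_ml
    dips <- cummax(cum) - cum
    if (any(dips > 0 & dips <= dip_tolerance)) {
      message(sum(dips > 0 & dips <= dip_tolerance),
              " cumulative dip(s) within tolerance clamped for reactor ", id)
    }
    dose <- 0
    fe <- NULL
    if (!is.null(cfg)) {
      crow <- cfg[cfg$reactor_id == id, ]
      if (nrow(crow) == 0) stop("no design metadata for reactor ", id)
      dose <- crow$dose_g_per_l[1]
      fe <- data.frame(day = crow$feed_day, vs_fed_g = crow$vs_fed_g)
    }
    out[[id]] <- gas_series(sub$time_days, cum, reactor_id = id,
                            dose_g_per_l = dose, feed_events = fe,
                            dip_tolerance = dip_tolerance)
  }
  out
}

#' Read feedstock compositions from a YAML config
#'
#' One mapping per feedstock label with keys matching the
#' [elemental_composition()] fields (\code{carbon_pct_ts},
#' \code{hydrogen_pct_ts}, ...).
#'
#' @param path YAML file.
#' @return Named list of \code{elemental_composition}.
#' @export
read_composition_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(lab) {
    do.call(elemental_composition, c(raw[[lab]], list(label = lab)))
  })
  names(out) <- names(raw)
  out
}

#' Run the full assay-analysis pipeline on an experiment
#'
#' Executes the chain end to end: theoretical uBMY accounting for the fed
#' substrate and inoculum (when compositions are given), first-order
#' depletion scheduling, per-reactor phase segmentation and per-g-VS
#' normalization, modified-Gompertz and first-order fits of the isolated
#' (final) phase, optional ARIMA order selection on each reactor's
#' whole-experiment cumulative yield, and the two relative-increase matrices
#' (final-phase BMP and whole-experiment BMY, from per-dose replicate means).
#'
#' @param experiment \code{bmp_experiment} or named list of [gas_series()]
#'   carrying feed events and doses.
#' @param inoculum [first_order_model()] used for the depletion schedule.
#' @param target,settle_days Scheduling parameters, see [design_plan()].
#' @param compositions Optional named list of [elemental_composition()];
#'   when it contains \code{substrate} and \code{inoculum} entries plus
#'   \code{substrate_gvs}/\code{inoculum_gvs} masses, the theoretical mixture
#'   uBMY is reported.
#' @param substrate_gvs,inoculum_gvs g VS of substrate / inoculum loaded.
#' @param molar_volume_ml Gas molar volume for the stoichiometry stage.
#' @param arima Either \code{FALSE} (skip), or a list of options:
#'   \code{p_max}, \code{q_max}, \code{d_max}, \code{downsample_to}
#'   (thin each series to about this many points before order selection).
#' @param rate_window_hr Smoothing window for peak extraction, hours.
#' @return Nested list of class \code{bmp_report} with elements
#'   \code{stoichiometry}, \code{schedule}, \code{reactors} (per-reactor
#'   phase fits and peaks), \code{doses} (per-dose summary table),
#'   \code{relative_increase} (two \code{ri_matrix} objects), \code{arima}
#'   (per reactor, if enabled) and \code{provenance}.
#' @export
run_pipeline <- function(experiment,
                         inoculum = first_order_model(3089.74, 0.13),
                         target = 0.99, settle_days = 14,
                         compositions = NULL,
                         substrate_gvs = NULL, inoculum_gvs = NULL,
                         molar_volume_ml = 22400,
                         arima = FALSE,
                         rate_window_hr = 1) {
  if (length(experiment) == 0) stop("empty experiment")
  first <- experiment[[1]]
  if (is.null(first$feed_events)) stop("reactors must carry feed events")
  horizon <- max(first$times)
  feed_days <- first$feed_events$day

  stoich <- NULL
  if (!is.null(compositions)) {
    pots <- lapply(compositions, ultimate_potentials,
                   molar_volume_ml = molar_volume_ml)
    stoich <- list(potentials = pots)
    if (!is.null(substrate_gvs) && !is.null(inoculum_gvs) &&
        all(c("substrate", "inoculum") %in% names(pots))) {
      ys <- list(ultimate_yield(pots$substrate, substrate_gvs),
                 ultimate_yield(pots$inoculum, inoculum_gvs))
      stoich$component_ubmy_ml <- vapply(ys, `[[`, numeric(1), "ubmy_ml")
      stoich$mixture_ubmy_ml <- mixture_ubmy(ys)
    }
  }

  plan <- design_plan(inoculum, target = target, settle_days = settle_days,
                      horizon = horizon, feed_days = feed_days,
                      feed_masses_gvs = first$feed_events$vs_fed_g)
  iso <- plan$isolated_phase_index

  reactors <- lapply(experiment, function(s) {
    phases <- segment_phases(s, horizon = horizon)
    final_phase <- phases[[iso]]
    norm <- normalize_per_vs(final_phase)
    g_fit <- fit_gompertz(norm$times, norm$cumulative)
    fo_fit <- fit_first_order(norm$times, norm$cumulative)
    rate <- production_rate(s, window_hr = rate_window_hr)
    peaks <- find_peaks(rate$time_days, rate$rate_ml_per_hr)
    list(reactor_id = s$reactor_id, dose = s$dose_g_per_l,
         final_phase_bmp = norm$cumulative[length(norm$cumulative)],
         total_bmy_ml = s$cumulative[length(s$cumulative)],
         gompertz = g_fit, first_order = fo_fit, peaks = peaks)
  })

  doses <- vapply(reactors, `[[`, numeric(1), "dose")
  per_dose <- do.call(rbind, lapply(sort(unique(doses)), function(d) {
    rs <- reactors[doses == d]
    data.frame(
      dose_g_per_l = d, n = length(rs),
      mean_final_phase_bmp = mean(vapply(rs, `[[`, numeric(1),
                                         "final_phase_bmp")),
      mean_total_bmy_ml = mean(vapply(rs, `[[`, numeric(1), "total_bmy_ml")),
      mean_bbmp = mean(vapply(rs, function(r) r$gompertz$params$bbmp,
                              numeric(1))),
      mean_rmax = mean(vapply(rs, function(r) r$gompertz$params$rmax,
                              numeric(1))),
      mean_lag = mean(vapply(rs, function(r) r$gompertz$params$lag_days,
                             numeric(1))),
      mean_k = mean(vapply(rs, function(r) r$first_order$params$k_per_day,
                           numeric(1))))
  }))

  ri <- NULL
  if (nrow(per_dose) >= 2) {
    bmp_v <- stats::setNames(per_dose$mean_final_phase_bmp,
                             per_dose$dose_g_per_l)
    bmy_v <- stats::setNames(per_dose$mean_total_bmy_ml,
                             per_dose$dose_g_per_l)
    ri <- list(phase_bmp = relative_increase_matrix(bmp_v, "phase_bmp"),
               total_bmy = relative_increase_matrix(bmy_v, "total_bmy"))
  }

  arima_out <- NULL
  if (!isFALSE(arima)) {
    opts <- utils::modifyList(
      list(p_max = 2, q_max = 2, d_max = 1, downsample_to = 600),
      if (is.list(arima)) arima else list())
    arima_out <- lapply(experiment, function(s) {
      y <- s$cumulative
      if (length(y) > opts$downsample_to) {
        y <- y[seq(1, length(y), length.out = opts$downsample_to)]
      }
      select_order(y, p_max = opts$p_max, q_max = opts$q_max,
                   d_max = opts$d_max)
    })
  }

  structure(
    list(stoichiometry = stoich, schedule = plan, reactors = reactors,
         doses = per_dose, relative_increase = ri, arima = arima_out,
         provenance = list(
           stoichiometry = "Buswell-Mueller balance at configured molar volume",
           schedule = "first-order depletion model",
           doses = "per-reactor final-phase fits, replicate means",
           relative_increase = "per-dose means, higher dose as denominator",
           arima = if (isFALSE(arima)) "disabled"
                   else "AIC-selected on training segment")),
    class = "bmp_report")
}

#' @export
print.bmp_report <- function(x, ...) {
  cat("BMP pipeline report:", length(x$reactors), "reactors,",
      nrow(x$doses), "doses\n")
  if (!is.null(x$stoichiometry$mixture_ubmy_ml)) {
    cat(sprintf("  theoretical mixture uBMY: %.1f mL CH4\n",
                x$stoichiometry$mixture_ubmy_ml))
  }
  cat(sprintf("  isolated phase %d starting day %g\n",
              x$schedule$isolated_phase_index,
              x$schedule$isolated_phase_start))
  print(x$doses, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to JSON + CSV tables
#'
#' Emits \code{report.json} (full nested report), \code{doses.csv} (per-dose
#' summary) and \code{ri_phase_bmp.csv}/\code{ri_total_bmy.csv} (the two
#' relative-increase matrices).
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bmp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- list(
    stoichiometry = report$stoichiometry,
    schedule = report$schedule[c("feed_days", "feed_masses_gvs",
                                 "depletion_day", "isolated_phase_start",
                                 "isolated_phase_index", "horizon")],
    doses = report$doses,
    reactors = lapply(report$reactors, function(r) {
      list(reactor_id = r$reactor_id, dose = r$dose,
           final_phase_bmp = r$final_phase_bmp,
           total_bmy_ml = r$total_bmy_ml,
           gompertz = r$gompertz$params[c("bbmp", "rmax", "lag_days")],
           gompertz_r2 = r$gompertz$diagnostics$r_squared,
           first_order = r$first_order$params[c("ubmy_ml", "k_per_day")],
           peaks = r$peaks)
    }),
    relative_increase = lapply(report$relative_increase, function(m) {
      as.data.frame(unclass(m))
    }),
    arima = lapply(report$arima, function(a) {
      list(order = as.list(a$order),
           validation_r2 = a$diagnostics$validation$r_squared,
           prediction_rmse = a$diagnostics$prediction$rmse)
    }),
    provenance = report$provenance)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(slim, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  doses_path <- file.path(dir, "doses.csv")
  utils::write.csv(report$doses, doses_path, row.names = FALSE)
  paths <- c(json_path, doses_path)
  for (nm in names(report$relative_increase)) {
    p <- file.path(dir, paste0("ri_", nm, ".csv"))
    utils::write.csv(unclass(report$relative_increase[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
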