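#' Configuration of the per-country analysis
#'
#' @param horizon Forecast horizon in years, >= 1 (default 8, the
#'   2020-2027 projection window for series observed over 2005-2019).
#' @param theta Weight of the observed-period mean in the synthetic
#'   indices, in `[0, 1]` (default 0.5).
#' @param observed_window Length-2 integer vector, inclusive year range
#'   for observed-period metric means. Default `NULL`: from the second
#'   observed year to the antepenultimate one (2006-2017 for a 2005-2019
#'   series), the block over which the published observed-period means are
#'   defined.
#' @param forecast_window Length-2 integer vector for the forecast-period
#'   means. Default `NULL`: from the second forecast year to the last one
#'   (2021-2027 for an 8-year horizon), or the single forecast year when
#'   `horizon = 1`.
#' @param mape_skip_first Should the reported headline MAPE exclude the
#'   anchored first year? (default `FALSE`; both modes are always
#'   reported).
#' @param reset_years Optional integer vector of years at which a
#'   display-only `cumulative_reset` column restarts its running total,
#'   reproducing the layout of the published tables. Growth metrics always
#'   use the continuous cumulative series.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(horizon = 8, theta = 0.5,
                            observed_window = NULL,
                            forecast_window = NULL,
                            mape_skip_first = FALSE,
                            reset_years = NULL) {
  horizon <- as.integer(horizon)
  if (length(horizon) != 1L || is.na(horizon) || horizon < 1L) {
    stop("`horizon` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("`theta` must be a single number in [0, 1]", call. = FALSE)
  }
  for (w in list(observed_window, forecast_window)) {
    if (!is.null(w) && (length(w) != 2L || w[1L] > w[2L])) {
      stop("windows must be length-2 ascending year ranges", call. = FALSE)
    }
  }
  structure(list(horizon = horizon, theta = theta,
                 observed_window = observed_window,
                 forecast_window = forecast_window,
                 mape_skip_first = isTRUE(mape_skip_first),
                 reset_years = reset_years),
            class = "analysis_config")
}

default_windows <- function(series_years, horizon, config) {
  ow <- config$observed_window
  if (is.null(ow)) {
    ow <- c(series_years[1L] + 1L, series_years[length(series_years)] - 2L)
  }
  fy <- series_years[length(series_years)] + seq_len(horizon)
  fw <- config$forecast_window
  if (is.null(fw)) {
    fw <- if (horizon >= 2L) c(fy[2L], fy[length(fy)]) else c(fy[1L], fy[1L])
  }
  list(observed = as.integer(ow), forecast = as.integer(fw))
}

#' Full grey analysis of one country
#'
#' Fits the NDGM, forecasts over the configured horizon, and assembles a
#' year-by-year table (observed value, fitted/forecast model value,
#' continuous cumulative total, RGR, Dt) together with a summary: MAPE in
#' both scoring conventions, observed- and forecast-window mean RGR and
#' mean Dt, and their theta-weighted synthetic indices. The cumulative
#' total continues through the forecast period without restarts; an
#' optional display-only reset column reproduces the published table
#' layout. One structured progress line per country is logged to stderr.
#'
#' @param series An [annual_series].
#' @param config An [analysis_config()].
#' @return An object of class `country_analysis`: a list with `label`,
#'   `table` (data frame), `summary` (list), `fit` (the [ndgm()] object)
#'   and `config`.
#' @examples
#' cvd <- cvd_mortality_series()
#' rep <- country_analysis(cvd$Pakistan, analysis_config())
#' rep$table[rep$table$year == 2006, ]
#' @export
country_analysis <- function(series, config = analysis_config()) {
  stopifnot(inherits(series, "annual_series"),
            inherits(config, "analysis_config"))
  fit <- ndgm(series)
  fc <- predict(fit, horizon = config$horizon)
  combined <- annual_series(series$label,
                            c(series$years, fc$years),
                            c(series$values, fc$values))
  growth <- rgr_series(combined)
  win <- default_windows(series$years, config$horizon, config)
  tab <- data.frame(
    year = combined$years,
    observed = c(series$values, rep(NA_real_, config$horizon)),
    model = c(fit$fitted, fc$values),
    cumulative = growth$cumulative,
    rgr = growth$rgr,
    dt = growth$dt
  )
  if (!is.null(config$reset_years)) {
    grp <- cumsum(tab$year %in% config$reset_years)
    tab$cumulative_reset <- stats::ave(combined$values, grp, FUN = cumsum)
  }
  mean_rgr_obs <- mean_window(growth, "rgr", win$observed[1L], win$observed[2L])
  mean_dt_obs <- mean_window(growth, "dt", win$observed[1L], win$observed[2L])
  mean_rgr_fc <- mean_window(growth, "rgr", win$forecast[1L], win$forecast[2L])
  mean_dt_fc <- mean_window(growth, "dt", win$forecast[1L], win$forecast[2L])
  summary <- list(
    mape_percent = fit$mape_percent,
    mape_skip_first_percent = fit$mape_skip_first_percent,
    mape_mode = if (config$mape_skip_first) "skip_first" else "all_years",
    mean_rgr_observed = mean_rgr_obs,
    mean_dt_observed = mean_dt_obs,
    mean_rgr_forecast = mean_rgr_fc,
    mean_dt_forecast = mean_dt_fc,
    rgr_synthetic = synthetic_index(mean_rgr_obs, mean_rgr_fc,
                                    config$theta)$value,
    dt_synthetic = synthetic_index(mean_dt_obs, mean_dt_fc,
                                   config$theta)$value,
    observed_window = win$observed,
    forecast_window = win$forecast,
    theta = config$theta,
    beta = fit$beta
  )
  message(sprintf(
    "country=%s n=%d beta1=%.6f beta2=%.4f beta3=%.4f beta4=%.4f mape=%.3f%% obs_window=%d-%d fc_window=%d-%d",
    series$label, length(series), fit$beta[["beta1"]], fit$beta[["beta2"]],
    fit$beta[["beta3"]], fit$beta[["beta4"]], fit$mape_percent,
    win$observed[1L], win$observed[2L], win$forecast[1L], win$forecast[2L]))
  structure(list(label = series$label, table = tab, summary = summary,
                 fit = fit, config = config),
            class = "country_analysis")
}

#' @export
print.country_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Grey analysis: %s (theta = %.2f)\n", x$label, s$theta))
  cat(sprintf("  MAPE %.3f%% (all) / %.3f%% (skip first)\n",
              s$mape_percent, s$mape_skip_first_percent))
  cat(sprintf("  mean RGR %.3f (obs %d-%d) / %.3f (fc %d-%d), synthetic %.3f\n",
              s$mean_rgr_observed, s$observed_window[1L], s$observed_window[2L],
              s$mean_rgr_forecast, s$forecast_window[1L], s$forecast_window[2L],
              s$rgr_synthetic))
  cat(sprintf("  mean Dt  %.3f / %.3f, synthetic %.3f\n",
              s$mean_dt_observed, s$mean_dt_forecast, s$dt_synthetic))
  invisible(x)
}

#' Full multi-country report
#'
#' Runs [country_analysis()] for every series and assembles the ranking
#' table (RGR descending and Dt ascending, for the observed-period,
#' forecast-period and synthetic means) and the MAPE summary (per country
#' in both scoring conventions, plus their averages). The report is fully
#' deterministic: regenerating it from the same inputs and configuration
#' is byte-identical.
#'
#' @param series_list A (named) list of [annual_series].
#' @param config An [analysis_config()].
#' @return An object of class `grey_report`: a list with `countries`
#'   (named list of [country_analysis()] results), `rankings` (data
#'   frame: `metric`, `period`, `rank`, `label`, `value`), `mape` (data
#'   frame with an `"Average"` row) and `config`.
#' @export
full_report <- function(series_list, config = analysis_config()) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  countries <- lapply(series_list, country_analysis, config = config)
  names(countries) <- vapply(countries, `[[`, "", "label")
  pull <- function(field) {
    vapply(countries, function(x) x$summary[[field]], numeric(1))
  }
  blocks <- list(
    list("rgr", "original", pull("mean_rgr_observed"), "descending"),
    list("rgr", "forecast", pull("mean_rgr_forecast"), "descending"),
    list("rgr", "synthetic", pull("rgr_synthetic"), "descending"),
    list("dt", "original", pull("mean_dt_observed"), "ascending"),
    list("dt", "forecast", pull("mean_dt_forecast"), "ascending"),
    list("dt", "synthetic", pull("dt_synthetic"), "ascending")
  )
  rankings <- do.call(rbind, lapply(blocks, function(b) {
    r <- rank_countries(stats::setNames(b[[3L]], names(countries)), b[[4L]])
    data.frame(metric = b[[1L]], period = b[[2L]], rank = r$rank,
               label = r$label, value = r$value, stringsAsFactors = FALSE)
  }))
  mape_df <- data.frame(
    country = c(names(countries), "Average"),
    mape_percent = c(pull("mape_percent"), mean(pull("mape_percent"))),
    mape_skip_first_percent = c(pull("mape_skip_first_percent"),
                                mean(pull("mape_skip_first_percent"))),
    stringsAsFactors = FALSE
  )
  mape_df$accuracy_percent <- 100 - mape_df$mape_percent
  structure(list(countries = countries, rankings = rankings,
                 mape = mape_df, config = config),
            class = "grey_report")
}

#' @export
print.grey_report <- function(x, ...) {
  cat(sprintf("Grey mortality report: %d countries, horizon %d, theta %.2f\n",
              length(x$countries), x$config$horizon, x$config$theta))
  ord <- x$rankings[x$rankings$metric == "rgr" &
                      x$rankings$period == "original", ]
  cat("  observed-period mean RGR ranking:",
      paste(sprintf("%s (%.3f)", ord$label, display_round(ord$value)),
            collapse = " > "), "\n")
  avg <- x$mape[x$mape$country == "Average", ]
  cat(sprintf("  average MAPE %.3f%% (all years) / %.3f%% (skip first)\n",
              avg$mape_percent, avg$mape_skip_first_percent))
  invisible(x)
}

#' Write a full report to CSV files
#'
#' Emits one `analysis_<country>.csv` per country (via
#' [write_report_table()], so every floating column gets a 3-decimal
#' display twin), plus `rankings.csv`, `mape_summary.csv` and
#' `run_config.csv` recording the analysis parameters.
#'
#' @param report A [full_report()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_full_report <- function(report, dir) {
  stopifnot(inherits(report, "grey_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cn in names(report$countries)) {
    p <- file.path(dir, paste0("analysis_", gsub("\\s+", "_", cn), ".csv"))
    write_report_table(report$countries[[cn]]$table, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "rankings.csv")
  write_report_table(report$rankings, p)
  paths <- c(paths, p)
  p <- file.path(dir, "mape_summary.csv")
  write_report_table(report$mape, p)
  paths <- c(paths, p)
  cfg <- report$config
  win <- report$countries[[1L]]$summary
  p <- file.path(dir, "run_config.csv")
  write_report_table(data.frame(
    parameter = c("horizon", "theta", "mape_mode", "observed_window",
                  "forecast_window"),
    value = c(cfg$horizon, cfg$theta,
              if (cfg$mape_skip_first) "skip_first" else "all_years",
              paste(win$observed_window, collapse = ":"),
              paste(win$forecast_window, collapse = ":")),
    stringsAsFactors = FALSE), p)
  invisible(c(paths, p))
}
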