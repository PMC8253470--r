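#' Relative growth rate and doubling time of a cumulative series
#'
#' Accumulates an annual series and computes, for each year from the
#' second onwards, the relative growth rate of the cumulative total
#' \deqn{RGR(t) = \ln(C_t / C_{t-1})}
#' (unit annual time step, so the `1/(t2 - t1)` factor is 1) and the
#' doubling-time statistic
#' \deqn{D_t = \ln(2 / RGR) = \ln 2 - \ln RGR,}
#' a strictly decreasing transform of RGR that is zero at `RGR = 2`.
#' Because the annual values are positive, the cumulative series is
#' strictly increasing, every RGR is positive and every `Dt` is defined.
#'
#' @param series An [annual_series] of length >= 2.
#' @return A data frame with one row per year: `year`, `cumulative`,
#'   `rgr` (`NA` for the first year) and `dt` (`NA` for the first year).
#' @examples
#' cvd <- cvd_mortality_series()
#' head(rgr_series(cvd$Kenya), 3)
#' @export
rgr_series <- function(series) {
  stopifnot(inherits(series, "annual_series"))
  if (length(series) < 2L) {
    stop("relative growth rates need at least 2 years", call. = FALSE)
  }
  cum <- cumsum(series$values)
  rgr <- c(NA_real_, diff(log(cum)))
  data.frame(year = series$years,
             cumulative = cum,
             rgr = rgr,
             dt = ifelse(is.na(rgr), NA_real_, log(2) - log(rgr)))
}

#' Doubling-time statistic for a relative growth rate
#'
#' `doubling_time(r)` is `log(2 / r)`, the time required for the
#' cumulative count to change two-fold at growth rate `r` under the
#' model's log-linear reading; it is strictly decreasing in `r`, zero at
#' `r = 2` and negative beyond. Non-positive rates have no doubling time
#' and are rejected rather than silently dropped.
#'
#' @param rgr Numeric vector of relative growth rates, all > 0.
#' @return `log(2) - log(rgr)`, in years.
#' @examples
#' doubling_time(2)  # exactly 0
#' @export
doubling_time <- function(rgr) {
  stopifnot(is.numeric(rgr))
  if (any(!is.finite(rgr)) || any(rgr <= 0)) {
    stop("doubling time is defined only for positive growth rates",
         call. = FALSE)
  }
  log(2) - log(rgr)
}

#' Mean of a growth metric over an inclusive year window
#'
#' @param records Data frame from [rgr_series()] (or any frame with a
#'   `year` column and the metric column).
#' @param metric `"rgr"` or `"dt"`.
#' @param start_year,end_year Inclusive window bounds; every year in the
#'   window must be present in `records` with a non-missing metric value.
#' @return The arithmetic mean of the metric over the window.
#' @export
mean_window <- function(records, metric = c("rgr", "dt"), start_year,
                        end_year) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(records), metric %in% names(records))
  if (start_year > end_year) {
    stop("empty window: start_year is after end_year", call. = FALSE)
  }
  want <- seq(start_year, end_year)
  idx <- match(want, records$year)
  vals <- records[[metric]][idx]
  if (anyNA(idx) || anyNA(vals)) {
    stop(sprintf("window %d-%d is not fully covered by the records",
                 start_year, end_year), call. = FALSE)
  }
  mean(vals)
}

#' Theta-weighted synthetic growth index
#'
#' Blends the observed-period and forecast-period mean of a growth metric
#' into a single index,
#' \deqn{value = \theta \cdot original + (1-\theta) \cdot forecast,}
#' with equal weights (`theta = 0.5`) by default. The result always lies
#' between the two means and moves monotonically from the forecast mean to
#' the original mean as `theta` goes from 0 to 1.
#'
#' @param original_mean Mean metric over the observed window.
#' @param forecast_mean Mean metric over the forecast window.
#' @param theta Weight on the observed-period mean, in `[0, 1]`.
#' @return An object of class `synthetic_index`: a list with `theta`,
#'   `original_mean`, `forecast_mean` and `value`.
#' @examples
#' synthetic_index(0.208, 0.254)  # value 0.231
#' @export
synthetic_index <- function(original_mean, forecast_mean, theta = 0.5) {
  stopifnot(is.numeric(original_mean), is.numeric(forecast_mean),
            length(original_mean) == 1L, length(forecast_mean) == 1L)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("`theta` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(theta = theta,
                 original_mean = original_mean,
                 forecast_mean = forecast_mean,
                 value = theta * original_mean + (1 - theta) * forecast_mean),
            class = "synthetic_index")
}

#' @export
print.synthetic_index <- function(x, ...) {
  cat(sprintf("synthetic index %.4f = %.2f * %.4f + %.2f * %.4f\n",
              x$value, x$theta, x$original_mean, 1 - x$theta,
              x$forecast_mean))
  invisible(x)
}

#' Rank labelled metric values
#'
#' Stable sort of labelled values: descending for growth rates ("greater
#' growth first"), ascending for doubling times ("less time first"). Ties
#' are broken by label in lexicographic order.
#'
#' @param values Named numeric vector (names are country labels).
#' @param direction `"descending"` or `"ascending"`.
#' @return A data frame with columns `label`, `value`, `rank` (1-based).
#' @examples
#' rank_countries(c(Sweden = 0.208, China = 0.236), "descending")
#' @export
rank_countries <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), length(values) >= 1L,
            !is.null(names(values)), all(nzchar(names(values))))
  key <- if (direction == "descending") -values else values
  o <- order(key, names(values), method = "radix")
  data.frame(label = names(values)[o],
             value = as.numeric(values)[o],
             rank = seq_along(values),
             stringsAsFactors = FALSE)
}
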