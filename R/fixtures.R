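#' Bundled cardiovascular mortality series, 2005-2019
#'
#' Annual cardiovascular-disease death counts for Pakistan, India, China,
#' Kenya, the USA and Sweden, 2005-2019 (15 years per country), compiled
#' from Our World in Data (Global Burden of Disease collaborative network,
#' WHO and IHME estimates) as tabulated in the original published
#' grey-system analysis of these six countries. Values are stored as plain
#' integers (thousands separators stripped at transcription).
#'
#' @return A named list of six [annual_series], each covering 2005-2019.
#' @examples
#' cvd <- cvd_mortality_series()
#' cvd$Pakistan
#' @seealso [published_ndgm_values()], [published_growth_summary()]
#' @export
cvd_mortality_series <- function() {
  path <- system.file("extdata", "cvd_deaths.csv", package = "greycast",
                      mustWork = TRUE)
  read_annual_series(path)
}

#' Published fitted NDGM values for the bundled series
#'
#' The fitted (restored order-0) model values reported alongside the
#' bundled data in the original published analysis, 2005-2019. These are
#' regression-test vectors, never model inputs: the exact software settings
#' behind them are unknown, so agreement is asserted at tolerance, not
#' equality. One cell (USA, 2019) is printed illegibly in the source table
#' and is omitted.
#'
#' @return A data frame with columns `country`, `year`, `value`.
#' @export
published_ndgm_values <- function() {
  path <- system.file("extdata", "ndgm_published.csv", package = "greycast",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published growth-metric summary for the bundled series
#'
#' The published per-country mean relative growth rates (RGR) and mean
#' doubling-time statistics (Dt) for the observed period, the forecast
#' period and their theta-weighted synthetic blends, as printed in the
#' original analysis' ranking table. Stored as reference values: the
#' per-country labels of the observed-period means are internally
#' inconsistent with the bundled raw data (recomputation reproduces the
#' printed *values* almost exactly but assigns several of them to
#' different countries), so tests treat these as published reference
#' cells, not as recomputable ground truth.
#'
#' @return A data frame with columns `country`, `metric` (`"rgr"` or
#'   `"dt"`), `period` (`"original"`, `"forecast"` or `"synthetic"`) and
#'   `value`.
#' @export
published_growth_summary <- function() {
  path <- system.file("extdata", "growth_summary_published.csv",
                      package = "greycast", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
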