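#' Annual count series
#'
#' An `annual_series` is a labelled sequence of strictly positive annual
#' counts on consecutive calendar years. It is the basic data container of
#' the package: the raw (order-0) series that the grey model accumulates,
#' fits and forecasts.
#'
#' @param label Country (or series) name, a single string.
#' @param years Integer vector of consecutive, ascending calendar years.
#' @param values Numeric vector of positive annual counts (deaths/year),
#'   same length as `years`.
#'
#' @return An object of class `annual_series`: a list with elements
#'   `label`, `years` and `values`.
#' @examples
#' annual_series("Kenya", 2005:2006, c(28096, 28709))
#' @export
annual_series <- function(label, years, values) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(label)) {
    stop("`label` must be a single non-empty string", call. = FALSE)
  }
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) == 0L || length(years) != length(values)) {
    stop("`years` and `values` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (anyNA(years) || anyNA(values) || any(!is.finite(values))) {
    stop(sprintf("series '%s' contains missing or non-finite entries", label),
         call. = FALSE)
  }
  if (length(years) > 1L && any(diff(years) != 1L)) {
    bad <- years[which(diff(years) != 1L)[1L]] + 1L
    stop(sprintf("series '%s': years must be strictly consecutive (problem at year %d)",
                 label, bad), call. = FALSE)
  }
  if (any(values <= 0)) {
    bad <- years[which(values <= 0)[1L]]
    stop(sprintf("series '%s': non-positive count in year %d", label, bad),
         call. = FALSE)
  }
  structure(list(label = label, years = years, values = values),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %s: %d years (%d-%d)\n",
              x$label, length(x$years), min(x$years), max(x$years)))
  print(stats::setNames(x$values, x$years))
  invisible(x)
}

#' @export
length.annual_series <- function(x) length(x$values)

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(country = x$label, year = x$years, deaths = x$values,
             stringsAsFactors = FALSE)
}

#' Read annual count series from a long-format CSV
#'
#' Expects a UTF-8 CSV with a header and columns `country`, `year`,
#' `deaths`. Rows are grouped by country and sorted by year; each country
#' becomes one [annual_series]. Validation problems raise errors rather
#' than being silently repaired: a missing or duplicated year is reported
#' with the country and year, a non-positive count with the offending
#' year, and an unparsable field with its line number.
#'
#' @param path Path to the CSV file.
#' @return A named list of [annual_series], one per country, in order of
#'   first appearance.
#' @export
read_annual_series <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("country", "year", "deaths")
  if (!all(needed %in% names(raw))) {
    stop(sprintf("CSV must have columns %s; found %s",
                 paste(needed, collapse = ", "),
                 paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  year <- suppressWarnings(as.numeric(raw$year))
  deaths <- suppressWarnings(as.numeric(raw$deaths))
  bad <- which(is.na(year) | is.na(deaths))
  if (length(bad) > 0L) {
    stop(sprintf("cannot parse row at line %d of %s", bad[1L] + 1L, path),
         call. = FALSE)
  }
  if (any(year != as.integer(year))) {
    stop(sprintf("non-integer year at line %d of %s",
                 which(year != as.integer(year))[1L] + 1L, path),
         call. = FALSE)
  }
  out <- list()
  for (cn in unique(raw$country)) {
    idx <- which(raw$country == cn)
    yy <- as.integer(year[idx])
    vv <- deaths[idx]
    o <- order(yy)
    yy <- yy[o]; vv <- vv[o]
    if (anyDuplicated(yy)) {
      stop(sprintf("series '%s': duplicate year %d", cn,
                   yy[anyDuplicated(yy)]), call. = FALSE)
    }
    if (length(yy) > 1L && any(diff(yy) != 1L)) {
      gap <- yy[which(diff(yy) != 1L)[1L]] + 1L
      stop(sprintf("series '%s': missing year %d", cn, gap), call. = FALSE)
    }
    out[[cn]] <- annual_series(cn, yy, vv)
  }
  out
}

#' Round half away from zero for display
#'
#' Result tables print values at 3 decimals using round-half-away-from-zero
#' (so 0.2555 prints as 0.256, -0.2555 as -0.256), while every comparison
#' and stored value keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' display_round(0.2555)  # 0.256
#' @export
display_round <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a result table as CSV with display columns
#'
#' Writes `records` to `path` with a stable column order: every
#' floating-point column is emitted at full precision and followed by a
#' companion `<name>_3dp` column holding the value rounded to 3 decimals
#' (half away from zero), matching the print precision of the report
#' tables. Re-reading the file reproduces the full-precision columns.
#'
#' @param records A data frame; an empty frame yields a header-only file.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_report_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- list()
  for (nm in names(records)) {
    col <- records[[nm]]
    out[[nm]] <- col
    if (is.double(col) && !all(is.na(col) | col == floor(col))) {
      out[[paste0(nm, "_3dp")]] <-
        ifelse(is.na(col), NA_character_,
               sprintf("%.3f", display_round(col, 3)))
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write table to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}
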