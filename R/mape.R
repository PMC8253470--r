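#' Mean absolute percentage error
#'
#' Scores a predicted series against the actual one by
#' \deqn{MAPE(\%) = \frac{100}{n}\sum_k \left|\frac{y(k)-\hat y(k)}{y(k)}\right|.}
#' The grey fit anchors its first value through the shift parameter, so
#' whether the first year belongs in the score is a convention; both modes
#' are supported and reports state which is used. The "accuracy level" is
#' `100 - MAPE`.
#'
#' @param actual Numeric vector (or [annual_series]) of observed values;
#'   all must be nonzero.
#' @param predicted Numeric vector (or [annual_series]) of the same length.
#' @param skip_first If `TRUE`, the first point is excluded from the score
#'   (default `FALSE`: all points scored).
#' @return An object of class `fit_score`: a list with `mape_percent`,
#'   `accuracy_percent` (`100 - mape_percent`), `n_points` and
#'   `skip_first`.
#' @examples
#' mape(c(100, 200), c(110, 180))  # 10%
#' @export
mape <- function(actual, predicted, skip_first = FALSE) {
  if (inherits(actual, "annual_series")) actual <- actual$values
  if (inherits(predicted, "annual_series")) predicted <- predicted$values
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted)) {
    stop(sprintf("length mismatch: actual has %d points, predicted %d",
                 length(actual), length(predicted)), call. = FALSE)
  }
  if (isTRUE(skip_first)) {
    actual <- actual[-1L]
    predicted <- predicted[-1L]
  }
  if (length(actual) == 0L) {
    stop("no points left to score", call. = FALSE)
  }
  if (any(actual == 0)) {
    stop("actual values must be nonzero for a percentage error",
         call. = FALSE)
  }
  m <- mean(abs((actual - predicted) / actual)) * 100
  structure(list(mape_percent = m,
                 accuracy_percent = 100 - m,
                 n_points = length(actual),
                 skip_first = isTRUE(skip_first)),
            class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat(sprintf("MAPE %.3f%% (accuracy %.3f%%) over %d points%s\n",
              x$mape_percent, x$accuracy_percent, x$n_points,
              if (x$skip_first) ", first point excluded" else ""))
  invisible(x)
}
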