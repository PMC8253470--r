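#' Accumulated generating operation (AGO)
#'
#' The AGO turns a raw (order-0) series into its running totals, the
#' order-1 series the grey recursion is defined on: `x1[k] = sum(x0[1:k])`.
#' Its exact inverse, [inverse_ago()], keeps the first value and takes
#' first differences, so `inverse_ago(ago(x))` is `x` for every series.
#'
#' @param x Numeric vector (order-0 values) or an [annual_series].
#' @return For a numeric vector, the cumulative sums; for an
#'   [annual_series], an [annual_series] with the same label and years and
#'   cumulative values.
#' @examples
#' ago(c(1, 2, 3))          # 1 3 6
#' inverse_ago(c(1, 3, 6))  # 1 2 3
#' @export
ago <- function(x) UseMethod("ago")

#' @export
ago.default <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  cumsum(as.numeric(x))
}

#' @export
ago.annual_series <- function(x) {
  annual_series(x$label, x$years, cumsum(x$values))
}

#' @rdname ago
#' @export
inverse_ago <- function(x) UseMethod("inverse_ago")

#' @export
inverse_ago.default <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  x <- as.numeric(x)
  c(x[1L], diff(x))
}

#' @export
inverse_ago.annual_series <- function(x) {
  annual_series(x$label, x$years, inverse_ago(x$values))
}
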