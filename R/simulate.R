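#' Simulate an NDGM-consistent annual count series
#'
#' Inverts the model: builds the order-1 series by the grey recursion
#' `x1(1) = x0 + shift`, `x1(L+1) = beta1 * x1(L) + beta2 * L + beta3`,
#' restores annual counts by inverse AGO, and (optionally) perturbs each
#' annual count multiplicatively by `exp(e)` with
#' `e ~ Normal(0, sigma^2)` — log-normal noise keeps counts positive and
#' mimics proportional registration error. With `sigma = 0` the output
#' satisfies the recursion exactly, so refitting recovers
#' `(beta1, beta2, beta3)` and the order-1 anchor `x0 + shift` to
#' numerical precision.
#'
#' Note on the planted shift: the emitted series carries the shift only
#' through its first value, so the anchor `x0 + shift` — not `shift`
#' itself — is the identifiable quantity on refit (`beta4` and the first
#' cumulative value are confounded; only their sum is identified).
#'
#' @param n_years Series length, >= 4.
#' @param beta1,beta2,beta3 Recursion coefficients.
#' @param x0 Initial annual count, > 0.
#' @param shift Planted anchor shift (default 0).
#' @param first_year Calendar origin (default 2005).
#' @param sigma Multiplicative log-normal noise scale, >= 0 (default 0).
#' @param seed Optional integer seed; the same seed always yields the same
#'   series, and the global random stream is left untouched.
#' @param label Series label (default `"simulated"`).
#' @return An [annual_series] of positive annual counts.
#' @examples
#' simulate_ndgm(10, beta1 = 1.05, beta2 = 10, beta3 = 100, x0 = 1000)
#' @export
simulate_ndgm <- function(n_years, beta1, beta2, beta3, x0, shift = 0,
                          first_year = 2005, sigma = 0, seed = NULL,
                          label = "simulated") {
  stopifnot(is.numeric(n_years), length(n_years) == 1L)
  n_years <- as.integer(n_years)
  if (n_years < 4L) stop("`n_years` must be at least 4", call. = FALSE)
  if (!is.numeric(x0) || x0 <= 0) stop("`x0` must be positive", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0) {
    stop("`sigma` must be non-negative", call. = FALSE)
  }
  x1 <- ndgm_recursion(x0 + shift, beta1, beta2, beta3, n_years)
  values <- inverse_ago(x1)
  years <- first_year + seq_len(n_years) - 1L
  if (sigma > 0) {
    values <- values * exp(local_rnorm(n_years, sigma, seed))
  }
  if (any(!is.finite(values) | values <= 0)) {
    bad <- years[which(!is.finite(values) | values <= 0)[1L]]
    stop(sprintf("generation failed: non-positive annual count in year %d (adjust parameters)",
                 bad), call. = FALSE)
  }
  annual_series(label, years, values)
}

# Seeded normal draws that leave the caller's random stream untouched.
local_rnorm <- function(n, sigma, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  stats::rnorm(n, mean = 0, sd = sigma)
}
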