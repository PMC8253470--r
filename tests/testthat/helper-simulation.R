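# Random generator specs for parameter-recovery checks. beta1 is kept away
# from the degenerate point 1 so the geometric closed form is exercised,
# and beta2 away from 0 so its relative error is meaningful. Draws that
# would produce a non-positive annual count are redrawn.
random_ndgm_spec <- function(seed) {
  for (try in 0:49) {
    set.seed(seed + 7919L * try)
    lo <- stats::runif(1) < 0.5
    spec <- list(
      beta1 = if (lo) stats::runif(1, 0.90, 0.98) else stats::runif(1, 1.02, 1.12),
      x0 = stats::runif(1, 200, 5000),
      n_years = sample(8:16, 1),
      seed = seed
    )
    spec$beta2 <- sample(c(-1, 1), 1) * stats::runif(1, 0.005, 0.05) * spec$x0
    spec$beta3 <- stats::runif(1, 0.2, 1.5) * spec$x0
    spec$shift <- stats::runif(1, -0.2, 0.2) * spec$x0
    series <- tryCatch(
      simulate_ndgm(spec$n_years, spec$beta1, spec$beta2, spec$beta3,
                    spec$x0, shift = spec$shift),
      error = function(e) NULL)
    if (!is.null(series)) {
      spec$series <- series
      return(spec)
    }
  }
  stop("could not draw a valid generator spec")
}

# Max relative error of the refitted recursion against a spec, in the
# identifiable parametrization: (beta1, beta2, beta3) and the order-1
# anchor x0 + shift (the planted shift and the first cumulative value are
# confounded; only their sum is identified).
recovery_error <- function(spec, fit) {
  truth <- c(spec$beta1, spec$beta2, spec$beta3, spec$x0 + spec$shift)
  est <- c(fit$beta[["beta1"]], fit$beta[["beta2"]], fit$beta[["beta3"]],
           fit$anchor)
  max(abs(est - truth) / abs(truth))
}

# Independent 1-D SSE oracle for the shift parameter: simulate the order-1
# recursion from x1[1] + b4 and accumulate squared errors over k = 2..n.
shift_sse <- function(b4, x1, beta1, beta2, beta3) {
  n <- length(x1)
  xh <- numeric(n)
  xh[1] <- x1[1] + b4
  for (L in seq_len(n - 1)) xh[L + 1] <- beta1 * xh[L] + beta2 * L + beta3
  sum((x1[-1] - xh[-1])^2)
}

# Numeric 1-D minimiser of the shift SSE. The objective is exactly
# quadratic in b4, so the vertex of the parabola through three separated
# evaluations is the exact minimiser; golden-section iterations hit the
# function-value rounding floor (SSE differences near the minimum drop
# below machine precision of the large SSE values) long before 1e-6.
shift_oracle <- function(x1, beta1, beta2, beta3) {
  h <- 0.25 * abs(x1[1])
  s <- vapply(c(-h, 0, h), shift_sse, numeric(1),
              x1 = x1, beta1 = beta1, beta2 = beta2, beta3 = beta3)
  h * (s[1] - s[3]) / (2 * (s[1] - 2 * s[2] + s[3]))
}

fixture_series <- function() cvd_mortality_series()
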