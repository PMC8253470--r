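#' Regression system of the NDGM(1,1)
#'
#' The non-homogeneous discrete grey model is the recursion on the
#' accumulated series
#' \deqn{\hat x^{(1)}(L+1) = \beta_1 \hat x^{(1)}(L) + \beta_2 L + \beta_3,}
#' so its linear parameters are estimated from the system with design row
#' `L` equal to `(x1[L], L, 1)` for `L = 1, ..., n-1` and response
#' `x1[L+1]`. At least three rows (n >= 4) are required for the three
#' linear parameters.
#'
#' @param x1 Numeric vector of accumulated (order-1) values, length >= 4.
#' @return A list with the `(n-1) x 3` design matrix `B` (columns `x1`,
#'   `L`, `const`) and the response vector `y`.
#' @export
ndgm_system <- function(x1) {
  stopifnot(is.numeric(x1))
  n <- length(x1)
  if (n < 4L) {
    stop(sprintf("insufficient data: NDGM needs at least 4 observations, got %d", n),
         call. = FALSE)
  }
  L <- seq_len(n - 1L)
  B <- cbind(x1 = x1[L], L = L, const = 1)
  list(B = B, y = x1[-1L])
}

#' Least-squares estimate of the NDGM linear parameters
#'
#' Solves the system from [ndgm_system()] by QR least squares, giving the
#' unique `(beta1, beta2, beta3)` minimising the residual sum of squares
#' (numerically equivalent to the normal-equation form
#' `solve(t(B) %*% B) %*% t(B) %*% y` on well-conditioned inputs).
#'
#' @param B Design matrix from [ndgm_system()].
#' @param y Response vector from [ndgm_system()].
#' @return Named numeric vector `c(beta1, beta2, beta3)`.
#' @export
ndgm_linear_params <- function(B, y) {
  stopifnot(is.matrix(B), ncol(B) == 3L, nrow(B) == length(y),
            nrow(B) >= 3L)
  qr_B <- qr(scale(B, center = FALSE,
                   scale = apply(abs(B), 2, max)))
  if (qr_B$rank < 3L) {
    stop("singular regression system: NDGM design matrix is rank-deficient (e.g. constant accumulated series)",
         call. = FALSE)
  }
  beta <- qr.coef(qr(B), y)
  stats::setNames(as.numeric(beta), c("beta1", "beta2", "beta3"))
}

# Geometric helper sums for the closed-form beta4 (beta1 != 1):
#   s_jb[L] = sum_{j=1}^{L} j * beta1^(L-j)
#   s_g[L]  = (1 - beta1^L) / (1 - beta1)
geom_sums <- function(beta1, L_max) {
  L <- seq_len(L_max)
  pw <- beta1^L
  s_jb <- vapply(L, function(l) sum(seq_len(l) * beta1^(l - seq_len(l))),
                 numeric(1))
  list(pw = pw, s_jb = s_jb, s_g = (1 - pw) / (1 - beta1))
}

#' Shift parameter beta4 of the NDGM
#'
#' The model anchors its order-1 recursion at
#' `xhat1(1) = x1[1] + beta4`; `beta4` is chosen to minimise the sum of
#' squared order-1 fitting errors over `k = 2, ..., n` (the `k = 1`
#' residual is identically zero by construction). With
#' `e(L) = x1[L+1] - beta1^L * x1[1] - beta2 * s_jb(L) - beta3 * s_g(L)`,
#' where `s_jb` and `s_g` are the geometric drift sums of the unrolled
#' recursion, the unique minimiser is
#' `beta4 = sum(e(L) * beta1^L) / sum(beta1^(2L))`.
#'
#' The geometric sums degenerate at `beta1 = 1`; within `tol` of that
#' point this function refuses and directs the caller to the degenerate
#' branch (handled automatically by [ndgm()]), where the sums are replaced
#' by their limits and the same objective is minimised directly.
#'
#' @param x1 Accumulated (order-1) series, length >= 4.
#' @param beta1,beta2,beta3 Linear parameters of the recursion.
#' @param tol Degeneracy tolerance on `|beta1 - 1|` (default `1e-9`).
#' @return The scalar `beta4`.
#' @export
ndgm_shift <- function(x1, beta1, beta2, beta3, tol = 1e-9) {
  stopifnot(is.numeric(x1), length(x1) >= 4L,
            is.finite(beta1), is.finite(beta2), is.finite(beta3))
  if (abs(beta1 - 1) <= tol) {
    stop("beta1 is within tolerance of 1: geometric sums degenerate; use the beta1 = 1 branch",
         call. = FALSE)
  }
  n <- length(x1)
  g <- geom_sums(beta1, n - 1L)
  e <- x1[-1L] - g$pw * x1[1L] - beta2 * g$s_jb - beta3 * g$s_g
  sum(e * g$pw) / sum(g$pw^2)
}

# SSE minimiser over beta4 valid for any beta1 (including 1): the fitted
# order-1 series is linear in beta4, xhat1(k) = A(k) + beta4 * beta1^(k-1),
# where A is the recursion run from the unshifted anchor x1[1].
ndgm_shift_direct <- function(x1, beta1, beta2, beta3) {
  n <- length(x1)
  A <- numeric(n)
  A[1L] <- x1[1L]
  for (L in seq_len(n - 1L)) A[L + 1L] <- beta1 * A[L] + beta2 * L + beta3
  g <- beta1^seq_len(n - 1L)
  sum((x1[-1L] - A[-1L]) * g) / sum(g^2)
}

ndgm_recursion <- function(anchor, beta1, beta2, beta3, n) {
  x <- numeric(n)
  x[1L] <- anchor
  for (L in seq_len(n - 1L)) x[L + 1L] <- beta1 * x[L] + beta2 * L + beta3
  x
}

#' Fit a non-homogeneous discrete grey model
#'
#' Accumulates the series ([ago()]), estimates `(beta1, beta2, beta3)` by
#' least squares ([ndgm_linear_params()]) and the anchor shift `beta4` as
#' the sum-of-squared-error minimiser ([ndgm_shift()]), runs the recursion
#' from `xhat1(1) = x1[1] + beta4`, and restores fitted annual values by
#' inverse AGO (with `xhat0(1) = xhat1(1)`). The fit is scored by mean
#' absolute percentage error in both conventions (including and excluding
#' the anchored first year).
#'
#' Degenerate inputs are handled on a dedicated branch: if the design
#' matrix is rank-deficient (a constant annual series makes the
#' accumulated column collinear with the year index) the model is fitted
#' with `beta1` fixed at 1, and if the estimated `beta1` falls within
#' `tol` of 1 the shift is obtained by direct SSE minimisation instead of
#' the geometric closed form. Both branches minimise the same objective.
#'
#' @param series An [annual_series] with at least 4 years.
#' @param tol Degeneracy tolerance on `|beta1 - 1|` (default `1e-9`).
#' @return An object of class `ndgm`: a list with `label`, `years`,
#'   `observed`, `beta` (named length-4 vector), `anchor`
#'   (`x1[1] + beta4`), `degenerate` flag, `fitted_order1`, `fitted`
#'   (restored order-0), `residuals`, `mape_percent` (all years) and
#'   `mape_skip_first_percent`.
#' @examples
#' cvd <- cvd_mortality_series()
#' fit <- ndgm(cvd$Pakistan)
#' fit
#' predict(fit, horizon = 8)
#' @export
ndgm <- function(series, tol = 1e-9) {
  stopifnot(inherits(series, "annual_series"))
  x0 <- series$values
  x1 <- ago(x0)
  sys <- ndgm_system(x1)
  degenerate <- FALSE
  beta <- tryCatch(ndgm_linear_params(sys$B, sys$y), error = function(e) e)
  if (inherits(beta, "error")) {
    if (!grepl("singular", conditionMessage(beta))) stop(beta)
    # beta1 = 1 submodel: regress x1[L+1] - x1[L] on (L, 1)
    degenerate <- TRUE
    cf <- qr.coef(qr(sys$B[, c("L", "const"), drop = FALSE]),
                  sys$y - sys$B[, "x1"])
    beta <- c(beta1 = 1, beta2 = as.numeric(cf[1L]),
              beta3 = as.numeric(cf[2L]))
  }
  if (abs(beta[["beta1"]] - 1) <= tol) {
    degenerate <- TRUE
    beta4 <- ndgm_shift_direct(x1, beta[["beta1"]], beta[["beta2"]],
                               beta[["beta3"]])
  } else {
    beta4 <- ndgm_shift(x1, beta[["beta1"]], beta[["beta2"]],
                        beta[["beta3"]], tol = tol)
  }
  anchor <- x1[1L] + beta4
  fitted1 <- ndgm_recursion(anchor, beta[["beta1"]], beta[["beta2"]],
                            beta[["beta3"]], length(x0))
  fitted0 <- inverse_ago(fitted1)
  structure(list(
    label = series$label,
    years = series$years,
    observed = x0,
    beta = c(beta, beta4 = beta4),
    anchor = anchor,
    degenerate = degenerate,
    fitted_order1 = fitted1,
    fitted = fitted0,
    residuals = x0 - fitted0,
    mape_percent = mape(x0, fitted0)$mape_percent,
    mape_skip_first_percent = mape(x0, fitted0, skip_first = TRUE)$mape_percent
  ), class = "ndgm")
}

#' Forecast future annual values from a fitted NDGM
#'
#' Continues the order-1 recursion beyond the observed years and restores
#' annual values by first differences, so the forecast years follow the
#' observed years consecutively. The default horizon of 8 years mirrors
#' the 2020-2027 projection window for series observed over 2005-2019.
#'
#' @param object A fitted [ndgm()] model.
#' @param horizon Number of future years, an integer >= 1 (default 8).
#' @param ... Unused.
#' @return An [annual_series] of forecast annual values.
#' @export
predict.ndgm <- function(object, horizon = 8, ...) {
  horizon <- as.integer(horizon)
  if (length(horizon) != 1L || is.na(horizon) || horizon < 1L) {
    stop("`horizon` must be a single integer >= 1", call. = FALSE)
  }
  n <- length(object$observed)
  b <- object$beta
  x1 <- c(object$fitted_order1, numeric(horizon))
  for (L in n:(n + horizon - 1L)) {
    x1[L + 1L] <- b[["beta1"]] * x1[L] + b[["beta2"]] * L + b[["beta3"]]
  }
  annual_series(object$label,
                object$years[n] + seq_len(horizon),
                diff(x1)[n:(n + horizon - 1L)])
}

#' @export
print.ndgm <- function(x, ...) {
  cat(sprintf("NDGM(1,1) fit: %s, %d years (%d-%d)%s\n",
              x$label, length(x$years), min(x$years), max(x$years),
              if (x$degenerate) " [degenerate beta1 = 1 branch]" else ""))
  cat("  beta:", paste(sprintf("%s = %.6g", names(x$beta), x$beta),
                       collapse = ", "), "\n")
  cat(sprintf("  MAPE: %.3f%% (all years), %.3f%% (excluding first)\n",
              x$mape_percent, x$mape_skip_first_percent))
  invisible(x)
}

#' @export
coef.ndgm <- function(object, ...) object$beta

#' @export
fitted.ndgm <- function(object, ...) object$fitted

#' @export
residuals.ndgm <- function(object, ...) object$residuals
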