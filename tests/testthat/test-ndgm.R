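test_that("accumulation and its inverse are exact mutual inverses", {
  expect_identical(ago(c(1, 2, 3)), c(1, 3, 6))
  expect_identical(inverse_ago(c(1, 3, 6)), c(1, 2, 3))
  expect_identical(ago(5), 5)
  expect_identical(inverse_ago(5), 5)

  kenya <- fixture_series()$Kenya
  expect_identical(ago(kenya$values)[2], 56805)
  expect_identical(inverse_ago(ago(kenya))$values, kenya$values)

  set.seed(42)
  for (i in 1:50) {
    x <- as.numeric(sample(1:100000, sample(1:30, 1), replace = TRUE))
    expect_identical(inverse_ago(ago(x)), x)
  }
})

test_that("regression system has rows (x1[L], L, 1) and response x1[L+1]", {
  sys <- ndgm_system(c(10, 20, 30, 40))
  expect_identical(unname(sys$B),
                   cbind(c(10, 20, 30), 1:3, c(1, 1, 1)))
  expect_identical(sys$y, c(20, 30, 40))
  expect_identical(nrow(ndgm_system(cumsum(fixture_series()$Pakistan$values))$B),
                   14L)
  expect_error(ndgm_system(c(1, 3, 6)), "insufficient data")
})

test_that("linear estimation matches an independent least-squares oracle", {
  set.seed(1)
  for (i in 1:20) {
    x1 <- cumsum(runif(12, 100, 1000))
    sys <- ndgm_system(x1)
    ours <- ndgm_linear_params(sys$B, sys$y)
    oracle <- stats::lm.fit(sys$B, sys$y)$coefficients
    expect_lt(max(abs(ours - oracle)), 1e-10 * max(abs(oracle)))
  }
})

test_that("linear estimation recovers exact recursion coefficients", {
  x1 <- numeric(10)
  x1[1] <- 1000
  for (L in 1:9) x1[L + 1] <- 1.05 * x1[L] + 10 * L + 100
  sys <- ndgm_system(x1)
  beta <- ndgm_linear_params(sys$B, sys$y)
  expect_lt(max(abs(beta - c(1.05, 10, 100)) / c(1.05, 10, 100)), 1e-8)
})

test_that("a constant accumulated increment yields a singular system", {
  sys <- ndgm_system(cumsum(rep(1000, 10)))
  expect_error(ndgm_linear_params(sys$B, sys$y), "singular")
})

test_that("closed-form shift recovers a planted anchor offset", {
  b <- c(1.06, 8, 900)
  x0 <- 1200
  n <- 12
  shifted <- numeric(n)
  shifted[1] <- x0 + 50
  for (L in 1:(n - 1)) shifted[L + 1] <- b[1] * shifted[L] + b[2] * L + b[3]
  x1 <- c(x0, shifted[-1])  # anchor unshifted, later totals from the shifted recursion
  expect_equal(ndgm_shift(x1, b[1], b[2], b[3]), 50, tolerance = 1e-8)

  unshifted <- numeric(n)
  unshifted[1] <- x0
  for (L in 1:(n - 1)) unshifted[L + 1] <- b[1] * unshifted[L] + b[2] * L + b[3]
  expect_lt(abs(ndgm_shift(unshifted, b[1], b[2], b[3])), 1e-8)

  expect_error(ndgm_shift(x1, 1, b[2], b[3]), "beta1 = 1 branch")
})

test_that("closed-form shift equals a numeric 1-D SSE minimiser", {
  for (i in 1:10) {
    spec <- random_ndgm_spec(300 + i)
    noisy <- simulate_ndgm(spec$n_years, spec$beta1, spec$beta2, spec$beta3,
                           spec$x0, sigma = 0.05, seed = 300 + i)
    x1 <- ago(noisy$values)
    sys <- ndgm_system(x1)
    beta <- ndgm_linear_params(sys$B, sys$y)
    b4 <- ndgm_shift(x1, beta[1], beta[2], beta[3])
    oracle <- shift_oracle(x1, beta[1], beta[2], beta[3])
    expect_lt(abs(b4 - oracle) / max(1, abs(b4)), 1e-6)
  }
})

test_that("fit is exact on noiseless generated series", {
  for (i in 1:10) {
    spec <- random_ndgm_spec(100 + i)
    fit <- ndgm(spec$series)
    expect_lt(recovery_error(spec, fit), 1e-6)
    expect_lt(fit$mape_percent, 1e-8)
  }
})

test_that("fitted values track the published model column for Pakistan", {
  fit <- ndgm(fixture_series()$Pakistan)
  expect_lt(abs(fit$fitted[2] - 297535) / 297535, 0.01)
})

test_that("constant series is fitted exactly on the degenerate branch", {
  fit <- ndgm(annual_series("const", 2001:2010, rep(1000, 10)))
  expect_true(fit$degenerate)
  expect_equal(fit$beta[["beta1"]], 1)
  expect_equal(unname(fitted(fit)), rep(1000, 10), tolerance = 1e-10)
  expect_lt(fit$mape_percent, 1e-8)
  # degenerate-branch shift agrees with the numeric SSE minimiser
  x1 <- cumsum(rep(1000, 10))
  opt <- stats::optimize(shift_sse, c(-500, 500), x1 = x1,
                         beta1 = 1, beta2 = 0, beta3 = 1000, tol = 1e-10)
  expect_equal(fit$beta[["beta4"]], opt$minimum, tolerance = 1e-4)
})

test_that("fitted order-1 series is increasing when restored values are positive", {
  for (fit in lapply(fixture_series(), ndgm)) {
    expect_true(all(fit$fitted > 0))
    expect_true(all(diff(fit$fitted_order1) > 0))
  }
})

test_that("forecasts continue the recursion on consecutive future years", {
  fit <- ndgm(fixture_series()$Pakistan)
  fc <- predict(fit, horizon = 8)
  expect_identical(fc$years, 2020:2027)
  expect_identical(predict(fit, horizon = 1)$values, fc$values[1])
  expect_error(predict(fit, horizon = 0), "horizon")
  expect_error(predict(fit, horizon = -3), "horizon")

  # forecasting an exactly-generated series reproduces the generator's continuation
  spec <- random_ndgm_spec(55)
  long <- simulate_ndgm(16, spec$beta1, spec$beta2, spec$beta3, spec$x0,
                        shift = spec$shift)
  obs <- annual_series(long$label, long$years[1:10], long$values[1:10])
  fc2 <- predict(ndgm(obs), horizon = 6)
  expect_equal(fc2$values, long$values[11:16], tolerance = 1e-6)
})
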