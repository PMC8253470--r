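test_that("per-year RGR and Dt reproduce the verified published cells", {
  cvd <- fixture_series()
  g <- lapply(cvd, rgr_series)
  cell <- function(cn, year, col) g[[cn]][g[[cn]]$year == year, col]

  expect_identical(display_round(cell("Pakistan", 2006, "rgr")), 0.699)
  expect_identical(display_round(cell("Pakistan", 2006, "dt")), 1.051)
  expect_identical(display_round(cell("Pakistan", 2007, "rgr")), 0.411)
  expect_identical(display_round(cell("Kenya", 2006, "rgr")), 0.704)
  expect_identical(display_round(cell("Kenya", 2006, "dt")), 1.044)
  expect_identical(display_round(cell("Kenya", 2007, "rgr")), 0.416)
  expect_identical(display_round(cell("Kenya", 2007, "dt")), 1.571)
  expect_identical(display_round(cell("USA", 2006, "rgr")), 0.684)
  expect_identical(display_round(cell("Sweden", 2006, "rgr")), 0.690)

  expect_identical(cell("Pakistan", 2006, "cumulative"), 594155)
  expect_identical(cell("Kenya", 2006, "cumulative"), 56805)
})

test_that("doubling time is the decreasing log transform of RGR", {
  expect_equal(doubling_time(2), 0, tolerance = 1e-15)
  expect_equal(doubling_time(2 / exp(1)), 1, tolerance = 1e-15)
  expect_equal(display_round(doubling_time(0.6990807)), 1.051)
  expect_error(doubling_time(0), "positive")
  expect_error(doubling_time(-0.1), "positive")
  expect_lt(doubling_time(3), 0)

  # Dt(r) + ln(r) = ln 2 identically
  set.seed(11)
  r <- exp(runif(200, -6, 2))
  expect_equal(doubling_time(r) + log(r), rep(log(2), 200),
               tolerance = 1e-12)
})

test_that("exact doubling of the cumulative total gives RGR = ln 2", {
  s <- annual_series("x", 2001:2004, c(1, 1, 2, 4))  # cumulative 1,2,4,8
  expect_equal(rgr_series(s)$rgr[-1], rep(log(2), 3), tolerance = 1e-12)
})

test_that("window means reproduce the recomputable published means", {
  cvd <- fixture_series()
  pak <- rgr_series(cvd$Pakistan)
  expect_identical(display_round(mean_window(pak, "rgr", 2006, 2017)), 0.223)
  expect_identical(display_round(mean_window(pak, "dt", 2006, 2017)), 2.397)
  ken <- rgr_series(cvd$Kenya)
  expect_identical(display_round(mean_window(ken, "dt", 2006, 2017)), 2.400)
  # Kenya's published observed-period mean RGR (0.212) is the mean of
  # misprinted per-year cells; the data themselves give 0.224.
  expect_identical(display_round(mean_window(ken, "rgr", 2006, 2017)), 0.224)

  expect_identical(mean_window(pak, "rgr", 2007, 2007), pak$rgr[pak$year == 2007])
  expect_error(mean_window(pak, "rgr", 2010, 2009), "empty window")
  expect_error(mean_window(pak, "rgr", 2005, 2010), "not fully covered")
  expect_error(mean_window(pak, "rgr", 2015, 2030), "not fully covered")
})

test_that("recomputed observed-period means reproduce the published value set but not its country labels", {
  cvd <- fixture_series()
  means <- vapply(cvd, function(s) mean_window(rgr_series(s), "rgr", 2006, 2017),
                  numeric(1))
  ranked <- rank_countries(means, "descending")
  # honest ranking from the raw data
  expect_identical(ranked$label,
                   c("India", "China", "Kenya", "Pakistan", "USA", "Sweden"))
  # the published summary prints the same ordered values, differently labelled
  pub <- published_growth_summary()
  pub <- pub[pub$metric == "rgr" & pub$period == "original", ]
  expect_identical(display_round(ranked$value), pub$value)
})

test_that("synthetic index blends the two period means", {
  sw <- synthetic_index(0.208, 0.254, theta = 0.5)
  expect_equal(sw$value, 0.231, tolerance = 1e-12)
  expect_identical(synthetic_index(0.208, 0.254, theta = 1)$value, 0.208)
  expect_identical(synthetic_index(0.208, 0.254, theta = 0)$value, 0.254)
  ch <- synthetic_index(0.236, 0.275, theta = 0.5)
  expect_equal(ch$value, 0.2555, tolerance = 1e-12)
  expect_error(synthetic_index(0.2, 0.3, theta = 1.5), "theta")
  expect_error(synthetic_index(0.2, 0.3, theta = -0.1), "theta")

  # monotone in theta, always between the endpoints
  th <- seq(0, 1, by = 0.1)
  v <- vapply(th, function(t) synthetic_index(0.1, 0.5, t)$value, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0.1 - 1e-15 & v <= 0.5 + 1e-15))
})

test_that("ranking sorts stably with alphabetical tie-break", {
  r <- rank_countries(c(China = 0.236, USA = 0.228, India = 0.224,
                        Pakistan = 0.223, Kenya = 0.212, Sweden = 0.208),
                      "descending")
  expect_identical(r$label,
                   c("China", "USA", "India", "Pakistan", "Kenya", "Sweden"))
  expect_identical(r$rank, 1:6)

  expect_identical(rank_countries(c(Solo = 1), "ascending")$rank, 1L)
  tie <- rank_countries(c(B = 2, A = 2), "descending")
  expect_identical(tie$label, c("A", "B"))

  # Dt is strictly decreasing in RGR, so the two orderings coincide
  means <- vapply(fixture_series(),
                  function(s) mean_window(rgr_series(s), "rgr", 2006, 2017),
                  numeric(1))
  by_rgr <- rank_countries(means, "descending")$label
  by_dt <- rank_countries(doubling_time(means), "ascending")$label
  expect_identical(by_rgr, by_dt)
})
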