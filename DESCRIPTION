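Package: greycast
Title: Non-Homogeneous Discrete Grey Forecasting of Annual Mortality Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the non-homogeneous discrete grey model NDGM(1,1) to short
    annual count series via the accumulated generating operation and least
    squares, forecasts future counts, and scores fits by mean absolute
    percentage error. Computes relative growth rates and doubling-time
    statistics on cumulative series, theta-weighted synthetic indices that
    blend observed- and forecast-period means, and country rankings. Bundles
    annual cardiovascular death counts (2005-2019) for Pakistan, India,
    China, Kenya, the USA and Sweden, and provides a seeded NDGM-based
    simulator so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
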