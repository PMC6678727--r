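Package: greymtd
Title: Fuzzy-Weighted Grey GM(1,1) Forecasting for Short Non-Negative Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the first-order one-variable grey model GM(1,1) with
    background values weighted by triangular fuzzy membership degrees derived
    from the mega-trend-diffusion (MTD) data profile, a small-sample technique
    for series as short as four observations. Provides one-step-ahead rolling
    backtesting with MAPE accuracy grading on the Lewis scale, rolling
    multi-step forecasting with forecast-augmented windows, a synthetic series
    generator for the grey exponential dynamics, a bundled annual emissions
    case-study series, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
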