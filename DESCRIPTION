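Package: borealNRV
Title: Reference Models of Natural Forest Age Structure for Boreal Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of the natural range of variation in boreal
    forest age structure and disturbance dynamics. Provides closed-form
    equilibrium age-class distributions for negative-exponential and Weibull
    time-since-disturbance regimes, a 3x3 reference matrix allocating
    landscape area across forest age classes (young, mid-aged, old) and
    disturbance dynamics types (gap, even-aged, cohort), a site-type-based
    bottom-up (ASIO-style) estimator, conservation reserve-need calculations
    from management-incompatible forest shares, a stochastic per-stand
    disturbance simulator that serves as a Monte-Carlo check on the analytic
    predictions, a management planner that translates the reference matrix
    into an age-class by cutting-method allocation and projects managed
    landscapes toward the reference, and a synthetic stand-table generator
    emulating a northern-Fennoscandian regional forest inventory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
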