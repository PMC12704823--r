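Package: coda24
Title: Compositional Analysis of 24-Hour Movement Behaviors and Weight Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compositional data analysis of accelerometer-derived
    24-hour movement behaviors (sleep, sedentary behavior, light and
    moderate-to-vigorous physical activity) in relation to a continuous health
    outcome such as percent total weight loss after metabolic bariatric
    surgery. Provides minute-epoch classification by vector-magnitude count
    cut-points with wear-time validity rules, closure of daily time use to
    1440 minutes, isometric log-ratio (ILR) pivot coordinates, linear
    regression of the outcome on ILR coordinates with covariate screening and
    an overall-composition F-test, isotemporal time-reallocation estimates
    with confidence intervals and feasibility flags, and a synthetic cohort
    generator with analytic ground truth for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
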