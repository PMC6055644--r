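Package: entericCH4
Title: Enteric Methane Prediction Equations for Lactating Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating enteric methane (CH4)
    prediction equations for lactating dairy cows from multi-study,
    multi-region databases. Provides energy-corrected milk and methane
    conversion factor arithmetic, region-wise interquartile-range outlier
    screening of CH4 yield and intensity, a registry of published
    production, yield and intensity prediction equations (including IPCC
    Tier 2 comparators), linear mixed-model fitting with study-within-
    research-group random intercepts, all-subsets BIC variable selection
    with iterative VIF collinearity pruning, leave-one-study-out
    cross-validation, a mean-square-prediction-error decomposition and
    concordance correlation evaluation suite, and a synthetic herd
    generator with known ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
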