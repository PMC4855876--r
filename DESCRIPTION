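Package: cusppower
Title: Power and Sample Size for Cusp Catastrophe Polynomial Regression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Guastello's polynomial regression operationalization of the
    cusp catastrophe model to change-score data, applies the classical
    three-coefficient decision rule for detecting a cusp, and compares the
    cusp fit against the four alternative linear models. Provides a
    Monte-Carlo simulation engine that estimates the statistical power of the
    cusp-detection procedure under a user-specified effect-size vector and
    residual noise level, builds power curves over a grid of sample sizes,
    and back-calculates the sample size required to reach a target power.
    Includes a seedable synthetic-data generator for the cusp polynomial
    model and CSV/JSON input-output helpers for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
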