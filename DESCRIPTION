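Package: semfma
Title: Frequentist Model Averaging for Structural Equation Models with
    Ordinal Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits structural equation models to ordinal data by two-step
    polychoric correlation estimation followed by unweighted, diagonally
    weighted, or fully weighted least squares, and combines a nested family
    of candidate models by frequentist model averaging under a local
    misspecification framework.  Provides mean-squared-error optimal model
    weights on the unit simplex with ordinal-data corrections to the risk
    criterion, model-averaging and full-model confidence intervals,
    residual-based goodness-of-fit statistics with mean-scaled and
    mean-and-variance adjusted chi-square corrections, robust RMSEA based
    sequential model selection, and a Monte Carlo simulation engine for
    coverage and rejection-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    quadprog,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
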