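Package: strokescale
Title: Construction and Validation of an Early Prognostic Scale for
    Ischemic Stroke Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build, apply and validate a weighted-point clinical
    prediction rule for 90-day ischemic stroke recovery from early bedside
    observations: NIHSS on days 1 and 3, a configurable panel of traditional
    Chinese medicine (TCM) symptoms and signs on days 1 and 3, and the
    Barthel Index at day 90.  Implements the full development pipeline --
    univariate factor screening (chi-square, t, Mann-Whitney, rank
    correlation), classification-tree cutpoint discretization of continuous
    predictors, multivariable logistic regression with backward elimination,
    point-weight assignment, and ROC/Youden cutoff selection -- together
    with the published 8-item scale, confusion-matrix validation metrics,
    and a synthetic cohort generator that reproduces the marginal structure
    the analysis assumes, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    optparse
Config/testthat/edition: 3
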