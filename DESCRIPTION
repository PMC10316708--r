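Package: dldscreen
Title: Screening Utility of a Parental Questionnaire for Developmental
    Language Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the screening utility of a parental
    linguistic concern questionnaire (PLCQ) for developmental language
    disorder (DLD) in preschool children. Implements risk-perception
    coding and cumulative concern scores, stratum-specific likelihood
    ratios (SSLR) with sparse-stratum collapsing, Bayesian pretest to
    posttest probability updating (optionally chained with a dichotomized
    biological/environmental covariate), effect-size based group
    comparisons with interpretation bands, logistic regression fitted by
    iteratively reweighted least squares with AIC stepwise question
    selection, and ROC/AUC evaluation with DeLong confidence intervals.
    Includes a latent-severity synthetic cohort generator so every stage
    of the analysis can be exercised and validated without child-level
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
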