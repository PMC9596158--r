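Package: consurv
Title: Consensus Multi-Cohort Survival Model Selection and Signature Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens consensus prognostic genes across multiple expression
    cohorts by univariate Cox regression, enumerates selector-by-modeler
    machine-learning combinations (penalized Cox, componentwise likelihood
    boosting, random survival forests, gradient boosting, survival support
    vector machines, supervised principal components, partial least squares
    Cox, stepwise Cox), tunes each by ten-fold cross-validation, ranks
    combinations by mean held-out concordance, and evaluates the winning gene
    signature (Kaplan-Meier and log-rank tests, IPCW time-dependent AUC,
    calibration curves, concordance comparisons, external-signature
    benchmarking). Includes a thresholded cell-line-to-patient drug
    repurposing screen and a seeded multi-cohort survival simulator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
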