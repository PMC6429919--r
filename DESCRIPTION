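Package: icuready
Title: Readiness-for-Discharge Classification from Routine ICU Data
Version: 0.1.0
Authors@R:
    person("ICU", "Informatics", email = "icu.informatics@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating readiness-for-discharge (RFD)
    classifiers from routinely collected intensive-care data. Codifies a set
    of fifteen nurse-led discharge criteria as thresholded tests with count
    and importance-weighted probability scores, labels ICU stays at callout
    with negative-class augmentation, extracts windowed physiological
    features with a sparse-data fallback, trains logistic and random-forest
    classifiers under a multiple-source cross-validation protocol with
    permutation feature importance, and reports ROC/PRC curves, partial
    AUROC, Brier score and operating-point metrics at a fixed specificity.
    Ships a synthetic two-cohort electronic-health-record generator with a
    planted physiology-to-outcome model so the full pipeline is testable
    without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
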