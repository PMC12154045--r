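Package: periostage
Title: Cascaded Logistic Staging of Periodontitis from Non-Clinical Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a three-function logistic cascade that screens for
    periodontitis and estimates its stage (healthy, stage I, II or III) from
    non-clinical inputs: an aMMP-8 mouth-rinse point-of-care test dichotomized
    at 20 ng/mL, the Visible Plaque Index, tooth count, smoking and diabetes
    status, and simple anthropometry. Provides the published scoring functions
    as fixtures, feature engineering for their composite predictors, a full
    diagnostic-test evaluation toolkit (sensitivity, specificity, F1, phi,
    Youden-optimal cut-offs, ROC/AUC, Wald confidence intervals,
    Hosmer-Lemeshow calibration), a logistic model-development framework
    (maximum-likelihood fitting with Wald inference, backward stepwise
    selection, VIF, Cook's distance, events-per-variable admissibility), and a
    synthetic cohort generator emulating the development study's stage-wise
    covariate structure.
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
    withr
Config/testthat/edition: 3
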