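Package: readmitw
Title: Thirty-Day Unplanned Readmission Prediction with Weather Exposure Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for predicting 30-day unplanned
    hospital readmission from common-data-model style electronic health records
    combined with ambient weather and air-quality exposure. Provides CDM-lite
    table readers with referential-integrity validation, condition/drug era
    derivation under a persistence gap, the Charlson comorbidity index (Romano
    adaptation), index-admission cohort construction with planned-readmission
    exclusion, a criterion-based weather score (W-score) summing advisory and
    warning points over the seven days after discharge, covariate assembly in
    clinical-only and clinical-plus-weather configurations, and tree-based model
    training (decision tree, random forest, AdaBoost, gradient boosting) with
    grid-search cross-validation, internal and external-site AUROC validation.
    A two-site synthetic EHR and weather generator with a configurable logistic
    outcome model makes every stage runnable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rpart,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
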