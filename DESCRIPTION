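Package: imudys
Title: Home-Based Dystonia Severity Estimation from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating the clinical severity of dystonia (0-4
    ordinal scale per limb per 5-second window) from four body-worn inertial
    measurement units. Covers synthetic-cohort simulation, sensor CSV ingest
    with linear-interpolation synchronization, resultant-channel derivation and
    windowing, time- and frequency-domain feature extraction with min-max
    normalization, feature-class screening and sequential forward selection,
    training of six classifier families under four settings with random
    oversampling and sequential model-based (Bayesian) hyperparameter tuning,
    and evaluation via k-fold and leave-two-subjects-out cross-validation with
    precision, recall, F1, RMSE and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    class,
    rpart,
    e1071,
    randomForest,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
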