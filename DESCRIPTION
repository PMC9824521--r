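Package: hrvstress
Title: Daily Physical-Stress Estimation from Wearable Heart Rate and
    In-Home Activity Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates morning and night physical-stress levels of elderly
    residents by fusing smartwatch heart-rate samples with in-home
    activity-interval logs. Heart-rate samples are converted to R-R
    intervals and summarised per activity with Lorenz (Poincare) plot
    ellipse statistics; activity durations and per-activity heart-rate
    variability are combined into gender-normalised activity, biometric
    and mixed indicators; twice-daily five-point Likert questionnaire
    answers are mapped to three stress classes and modelled with an
    imbalance-aware ensemble (SMOTE oversampling, seeded random
    undersampling with replacement, bagged random forests with majority
    voting). A synthetic-cohort generator with a latent daily stress
    state makes every stage testable without access to private study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
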