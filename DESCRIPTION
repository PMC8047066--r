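Package: mssignal
Title: Motion-Sickness Biosignal Feature Extraction, Symptom Indexes and
    Classifier Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for studying motion sickness from
    multimodal biosignals recorded on a wave-motion platform: a synthetic
    cohort generator producing protocol-structured 64-channel EEG,
    bilateral gastrocnemius EMG and heart-rate recordings coupled to
    ordinal symptom questionnaires; extraction of 19 biometric features
    (EEG relative band powers via Welch's method, EMG spectral-band shares
    and rectified-signal areas, heart-rate mean and variability);
    computation of eight cohort-relative binary motion-sickness indexes
    from 13-item symptom questionnaires, including a weighted symptom sum;
    Mann-Whitney univariate screening of every feature against every
    index; and a repeated stratified 10-fold benchmark of six classifier
    families with random-forest feature-importance ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    xgboost,
    e1071,
    rpart,
    nnet,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
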