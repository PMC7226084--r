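Package: hfopipe
Title: Two-Step Detection and Classification of High-Frequency Oscillations in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting high-frequency oscillations (HFOs) in
    intracranial EEG and classifying them into ripples, fast ripples, and
    fast ripples co-occurring with ripples. Provides a seeded synthetic
    annotated-iEEG generator, zero-phase band filtering and fixed-window
    energy-feature extraction (line length, short-time energy, RMS, Teager
    energy in three bands), a balanced binary detection step with five
    classifier families and hyperparameter tuning, a three-class step with
    ADASYN adaptive synthetic oversampling applied inside training folds,
    and rank-based model comparison (Friedman test with Nemenyi, Holm and
    Bergmann-Hommel post-hoc procedures). Includes EDF and plain-text
    readers/writers so real and synthetic recordings flow through identical
    code paths, and a seeded end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    MASS,
    e1071,
    glmnet,
    ranger,
    pROC,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
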