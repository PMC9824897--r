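Package: hybridseek
Title: Hybrid Seek Optimization and Weighted Ensemble Classification for EEG Seizure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting epileptic seizures from multi-channel EEG.
    Implements EDF reading and writing, band-pass preprocessing and window
    labelling (preictal versus interictal), decomposition into the five
    classical EEG frequency bands, statistical, wavelet-energy and entropy
    features, a hybrid crow-search/sparrow-search ("hybrid seek")
    metaheuristic used for wrapper feature selection and fusion-weight
    tuning, and a weighted ensemble of AdaBoost, random-forest and
    decision-tree classifiers evaluated by accuracy, sensitivity and
    specificity under training-percentage and k-fold protocols. A seeded
    synthetic EEG generator with planted preictal signatures makes the whole
    pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
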