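Package: eegconn
Title: Directed EEG Connectivity Features for Emotion and Stress Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of directed (effective) connectivity from
    multichannel EEG recordings and its use for affect and stress
    classification.  Implements multivariate autoregressive (MVAR)
    modelling by Yule-Walker with the derived directed transfer function
    (DTF) and (generalized) partial directed coherence (PDC/GPDC), the
    phase slope index (PSI) with jackknife standardization over Welch
    segments, a seven-band filter bank over 4-32 Hz, SAM-based binary
    valence/arousal labelling, perceived-stress grouping, Fisher-ratio
    feature selection with leave-one-out KNN/SVM classification, and
    Welch t-test group comparison of averaged-PSI channel flux maps.  A
    synthetic cohort generator with known directed coupling provides a
    ground-truth test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
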