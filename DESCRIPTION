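Package: gcq
Title: Granger-Causality Quantification of Multichannel EEG Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for directed-connectivity analysis of multichannel EEG and
    valence-arousal emotion classification. Implements discrete-wavelet
    extraction of the classical EEG frequency bands, combination of a 32-channel
    10-20 montage into six bilateral brain areas, min-max signal normalization,
    pairwise Granger-causality F-statistic connectivity matrices, a
    thresholded-sum scalar connectivity quantifier, and one-vs-all KNN/SVM
    evaluation with accuracy, sensitivity and F1 reporting over cross-validation
    and neighbourhood-size sweeps. A vector-autoregressive synthetic EEG
    generator with known directed coupling provides ground truth for testing
    the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071
Suggests:
    testthat (>= 3.0.0),
    class,
    lmtest,
    jsonlite,
    withr
Config/testthat/edition: 3
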