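Package: ieegfocus
Title: Epileptic Focus Localization from Interictal iEEG via Multiband
    Entropy Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies seizure-onset-zone (SOZ) channels from interictal
    intracranial EEG using high-frequency (100-600 Hz) filter-bank
    decomposition into 50 Hz subbands, eight entropy features per subband
    (approximate, sample, permutation, spectral Shannon/Renyi/Tsallis and
    two bispectral phase entropies), sparse linear discriminant feature
    selection, ADASYN oversampling of the minority (focal) class, and an
    RBF-kernel SVM evaluated with segment-wise cross-validation.  Segment
    detections are aggregated into per-channel counts whose thresholded
    ROC yields a channel-level AUC for focus identification.  Includes a
    synthetic interictal iEEG generator (1/f background plus
    Poisson-timed high-frequency oscillatory bursts) so the full pipeline
    is testable without clinical recordings, and minimal EDF and
    delimited-matrix readers/writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
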