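Package: emdeeg
Title: Empirical Mode Decomposition and IMF Selection for Epileptic EEG
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pre-seizure and seizure EEG segments
    with empirical mode decomposition (EMD) and its ensemble variant
    (EEMD). Implements cubic-spline sifting, ensemble averaging over
    noise-perturbed decompositions, a db4 discrete-wavelet baseline, a
    hybrid intrinsic-mode-function selection procedure combining energy,
    correlation, power-spectral-distance and t-test rankings with a
    histogram consensus, time-domain, spectral and nonlinear (rescaled-range
    Hurst exponent, Higuchi fractal dimension) feature banks, and a
    stratified cross-validated classification harness (SVM, k-nearest
    neighbours, naive Bayes, logistic regression) with confusion-derived
    performance metrics and a hemisphere summary. A seeded synthetic EEG
    generator emulating 100 Hz, one-minute, ten-channel pre-seizure and
    seizure epochs allows the full pipeline to run without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
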