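Package: compen
Title: Complexity-Entropy Fusion Analysis of Emotional EEG for Gender Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for gender recognition from emotional
    multichannel EEG. Provides a synthetic cohort generator with controllable
    long-range dependence (fractional Gaussian noise by circulant embedding)
    and signal irregularity (MIX processes), wavelet denoising (Symlet-9,
    level-4 discrete wavelet transform with per-level SURE soft thresholding)
    preceded by notch and Butterworth filtering, Hurst exponent estimation by
    rescaled-range analysis, amplitude-aware permutation entropy, fusion of
    both feature families into a combined complexity-entropy feature set,
    two-way ANOVA of gender by emotion, and SMOTE-balanced stratified
    cross-validated classification with k-nearest-neighbour and RBF-kernel
    support vector machine classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
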