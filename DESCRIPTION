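Package: semgcurl
Title: Sample-Entropy Event Detection and Feature-Based Classification of
    Isotonic-Contraction Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multi-channel surface
    electromyography (sEMG) recorded during alternating dumbbell curls
    (isotonic contraction). Provides a synthetic 8-channel curl-trial
    generator with ground-truth burst intervals; zero-phase Butterworth
    band-pass preprocessing with half-wave rectification and moving-average
    smoothing; sliding-window sample-entropy event detection with
    anti-shake onset/offset logic and interval propagation to same-arm
    channels; a 63-value time-domain and frequency-domain feature bank
    (including autoregressive coefficients, spectral moments and Haar
    wavelet-packet node energies); staged feature reduction driven by
    intraclass-correlation redundancy and two-sample t-test significance;
    and repeated stratified 10-fold cross-validation of LDA, quadratic and
    radial SVM, and subspace-discriminant classifiers, with decibel-scaled
    significance comparisons and one-way ANOVA with Tukey HSD post hoc
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
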