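Package: phonotrf
Title: Temporal Response Functions for Phonological-Feature Tracking in
    Developmental EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward encoding (temporal response function, TRF) analysis of
    continuous-speech EEG with an emphasis on infant and early-childhood data.
    Builds time-aligned predictors from phoneme-level annotations (binary
    phonological-feature step functions, log-spaced spectrogram bands, an
    autocorrelation pitch track), cleans multichannel EEG with an automated
    pipeline (FIR filtering, bad-channel detection, wavelet thresholding,
    spherical-spline interpolation, linked-mastoid referencing, amplitude-based
    epoch rejection), estimates ridge-regularized TRFs with cross-validated
    prediction accuracy and a time-shift permutation baseline, and provides the
    group-level mixed-effects layer relating feature timing statistics
    (duration, occurrence, pitch similarity) to the developmental trajectory of
    prediction accuracy. A synthetic-data module generates speech-like feature
    streams and simulated EEG with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
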