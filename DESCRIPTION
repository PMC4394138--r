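Package: neoseize
Title: Neonatal EEG Seizure Detection, Visualization and Audification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A probabilistic multi-channel neonatal EEG seizure detector and
    the decision-support outputs built on it. Implements the full detection
    chain (bipolar montage derivation, anti-aliased resampling to 32 Hz,
    8 s epochs with 50% overlap, a 55-feature time/frequency/information
    registry, anisotropic normalization, a support vector machine with
    sigmoid probability calibration, moving-average smoothing, max-fusion
    across channels, and threshold plus collar binary decisions), the three
    clinical visualization transforms (amplitude-integrated EEG with a
    semilogarithmic display scale, binary and probabilistic traces, a
    10-colour spatio-temporal probability colormap), algorithm-driven EEG
    audification via a phase vocoder, and the evaluation machinery (epoch,
    event and patient level metrics, two orderings of AUC computation, and
    a threshold-selection guide with bootstrap confidence bounds). A
    synthetic neonatal EEG generator with ground-truth annotations makes
    every stage testable without clinical recordings.
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
    signal,
    e1071,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    patchwork,
    withr
Config/testthat/edition: 3
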