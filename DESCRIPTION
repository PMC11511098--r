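Package: semgdiscrim
Title: Forearm Surface EMG Features and Discriminant Screening for Hand Osteoarthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel forearm surface electromyography
    (sEMG) recorded during functional hand tasks, oriented to screening for hand
    osteoarthritis. Implements zero-phase Butterworth conditioning of raw
    signals, rectified Gaussian-smoothed amplitude envelopes resampled to a
    common frame count, three amplitude-normalization schemes (task maximum,
    maximal voluntary contraction, and maximal-effort grasping), amplitude
    (median, range) and waveform (zero-crossing rate, enhanced wavelength)
    feature extraction with per-participant min-max rescaling, normality-gated
    two-group comparisons with sign matrices, a mixed repeated-measures ANOVA
    with Tukey's-B homogeneous subsets, Box's M, stepwise linear discriminant
    analysis selected by Wilks' lambda with leave-one-out cross-validation, a
    set of frozen published discriminant classifiers, and a seeded synthetic
    two-group sEMG cohort generator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
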