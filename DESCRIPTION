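Package: somnostage
Title: Automated Sleep-Stage Scoring, Agreement Statistics, and
    Synthetic Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Epoch-based sleep staging from polysomnography: EDF signal
    input/output on the standard six-EEG/two-EOG/one-EMG montage,
    per-epoch feature extraction (multitaper band-power fractions over
    2-s sub-epochs, spectral power ratios, line length, kurtosis, EOG
    band energy, EMG energy), three small sequence classifiers
    (convolutional, recurrent, and their composition) with subject-level
    splitting and best-model selection, and inter-rater agreement
    statistics (Cohen's kappa with an interpretation scale, specific
    positive/negative/overall agreement, subject-resampled bootstrap
    confidence intervals).  A seed-reproducible synthetic
    polysomnography generator emulates stage-dependent spectral content
    so every component is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
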