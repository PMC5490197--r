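Package: spindlekit
Title: Automated Sleep Spindle Detection and Characterization from Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale automated characterization of sleep
    spindles in stage N2 sleep from polysomnography. Reads European Data
    Format (EDF) recordings with per-epoch stage annotations, performs
    epoch-level quality control (spectral aberrance, Hjorth-parameter
    outlier filtering, clipping detection), corrects cardiac interference
    in the EEG by R-peak-locked ensemble average subtraction, detects
    spindles with a complex Morlet wavelet detector (plus a band-pass/RMS
    alternative), extracts per-spindle properties, computes Welch band
    power, segments the hypnogram into NREM sleep cycles with temporal
    covariates, and aggregates per-individual measures with
    minimum-data, outlier and channel-merging rules. A ground-truthed
    synthetic polysomnography generator supports end-to-end validation
    without access-controlled recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    signal,
    generics,
    ggplot2,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
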