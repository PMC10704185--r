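Package: etalaser
Title: Two-Photon Excitation Efficiency of Ultrafast Pulsed Lasers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking ultrashort pulsed lasers used in
    two-photon (2p) fluorescence microscopy. Simulates femtosecond pulse
    power profiles (sech-squared, Gaussian, square, and distorted
    multi-lobe pulses), computes intensity autocorrelation functions and
    deconvolved pulse durations, predicts relative 2p fluorescence from
    pulse traces or from scalar laser parameters, and estimates the 2p
    excitation efficiency statistic eta that compares a test laser
    against a reference laser after adjusting for repetition rate and
    pulse duration. Includes a camera-image pipeline that extracts
    background-subtracted, exposure-normalized peak intensities and
    lateral/axial FWHM of the excitation volume from 16-bit frames, and
    a synthetic-data generator that emulates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
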