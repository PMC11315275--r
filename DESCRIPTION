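Package: puretone
Title: Automated Pure-Tone Audiometry: Calibration, Adaptive Staircases,
    Simulated Listeners and Agreement Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Software core of an automated standard and extended
    high-frequency pure-tone audiometer, without any audio hardware.
    Provides RETSPL-based calibration mapping between hearing level
    (dB HL), digital signal amplification and sound pressure level
    (dB SPL); synthesis of the calibrated five-beep tone-burst stimulus
    with WAV export; a Hughson-Westlake adaptive staircase implemented
    as a pure state machine with device-specific threshold-validation
    rules; simulated psychometric listeners and a two-device study
    emulator; and per-frequency Bland-Altman limits-of-agreement
    analysis of paired audiograms, with tidy outputs and ggplot2
    visualisations throughout.
License: MIT
Encoding: UTF-8
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
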