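Package: fuzzppg
Title: Fuzzy-Inspired Classification of Photoplethysmography Signals for
    Cardiovascular Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models cardiovascular-disorder risk from single-channel
    photoplethysmography (PPG) time series. Records are cut into two-second
    segments, eight waveform statistics (energy, variance, approximate
    entropy, mean, standard deviation, skewness, kurtosis, peak maximum)
    are extracted per segment, and a bank of seven two-input Mamdani fuzzy
    subsystems encodes each segment as a seven-letter weighted code word.
    Per-patient code-word streams are compressed by four population
    metaheuristics (differential search, shuffled frog leaping, wolf
    search, animal migration optimization) toward a singleton risk
    pattern, then classified with six classical classifiers under
    stratified 10-fold cross-validation. Includes a two-class synthetic
    PPG generator, rhythmicity and rescaled-range Hurst diagnostics, and
    the bespoke evaluation metrics (performance index, good detection
    rate) used in this literature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    pracma,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
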