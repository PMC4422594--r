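Package: eegindex
Title: Model-Based Neurophysiological Indices from EEG for Media Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains per-subject two-class Fisher linear discriminant models
    on spectral EEG band-power features (ANOVA-seeded greedy forward
    selection with tenfold cross-validation) and applies them to novel EEG
    recorded while viewing media clips, producing posterior-probability
    index time series for affective and cognitive states (happiness,
    surprise, attention). Includes quarter-second band-power feature
    extraction on the 14-channel Emotiv montage, index normalisation to
    [-1, 1], clip summarisation and ranking, supra-threshold peak
    localisation in elapsed time, behavioural rank-to-points scoring with
    group comparisons, a reproducible synthetic EEG session generator with
    planted band-limited effects for validation, CSV/EDF recording I/O and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
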