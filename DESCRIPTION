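Package: clicktypes
Title: Discovery and Classification of Odontocete Echolocation Click Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for long-term passive acoustic monitoring of toothed
    whales (odontocetes). Implements a two-stage impulse detector for
    echolocation clicks in calibrated high-frequency recordings, per-click
    spectral feature extraction, two-phase unsupervised click-type discovery
    by Chinese whispers graph clustering of 5-minute bin summaries,
    descriptive type statistics (median peak frequency, -3 dB bandwidth,
    modal inter-click interval), a feed-forward neural-network bin
    classifier with balanced-class training and false-positive-rate
    estimation, and effort-normalized seasonal acoustic presence
    aggregation with matching against visual sighting records. Includes a
    calibrated synthetic soundscape generator (click trains, sonar and
    snapping-shrimp confounders) so the whole pipeline can be exercised and
    validated without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    geosphere,
    ggplot2,
    patchwork,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
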