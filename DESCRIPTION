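Package: microstate
Title: EEG Microstate Analysis with Automatic Model-Order Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microstate analysis of multichannel EEG: global field power (GFP)
    computation and peak-topography extraction, polarity-invariant modified
    K-means clustering of scalp topographies, automatic selection of the
    number of microstates by a Krzanowski-Lai-style criterion on the global
    explained variance (GEV) curve, template backfitting with windowed
    temporal smoothing, microstate temporal and spatial parameter extraction
    (occurrence, duration, coverage, transition probabilities, per-class GEV,
    mean GFP, mean spatial correlation), band-power features, nonparametric
    group comparisons for emotion conditions, and a ground-truthed synthetic
    EEG generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
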