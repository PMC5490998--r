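Package: surfassoc
Title: Surface-Association Behaviour of Tropical Tuna from Archival Tag Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic classification of archival-tag depth and water
    temperature time-series from tropical tuna into shallow/warm and deep/cold
    behavioural states with per-individual two-state multivariate-normal hidden
    Markov models. Derives a 24-hour running-mean surface-association
    probability, extracts threshold-defined surface-association events with
    per-fish summary metrics (event rates, durations, outliers, Hartigan's dip
    test of bimodality), and combines event probabilities with light-based
    geolocation confidence ellipses into a 0.1 degree raster of mean
    surface-association probability. Includes a synthetic tag-data generator
    with retained ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
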