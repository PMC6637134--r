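Package: mousecp
Title: Changepoint Detection of Visually Evoked Behavioural Responses in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of innate behavioural responses of mice to
    visual stimuli in open-field video. Tracks dense body landmarks with a
    Harris-corner image pyramid, rejects mismatches with clustered
    rotation-plus-translation (partial Procrustes) motion models selected by a
    minimum-description-length criterion, converts landmark speeds into
    multivariate speed-quantile time series, segments those series with an
    exact penalised changepoint algorithm (PELT) whose penalty is chosen from
    the CROPS penalty path via segmented ("knee") regression, and summarises
    trial-level responses (changepoint-rate differences, speed responses, sign
    tests, permutation habituation tests). Includes seeded synthetic-data
    generators (videos, rigid-motion landmark clouds, piecewise-constant
    series) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    png,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
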