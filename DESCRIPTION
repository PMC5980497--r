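Package: nichemetrics
Title: Evaluation Metrics for Presence-Only Ecological Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation toolkit for presence-only ecological niche models
    (species distribution models). Implements geographic-space metrics
    (omission-rate thresholding, proportional predicted area, one-tailed
    cumulative binomial tests, bootstrap partial ROC AUC ratios, AIC/AICc
    with explicit parameter-counting rules for quadratic GLMs and
    classification models) and environmental-space metrics built on
    minimum-volume enclosing ellipsoids: interpolation/extrapolation
    frequencies, Jaccard niche similarity, and degree of extrapolation.
    Includes a seeded virtual-species scenario generator (correlated
    environmental layers, a Gaussian true niche, geographically disjoint
    calibration populations with a held-out evaluation population, and
    contrasting pseudo-model suitability surfaces) so the whole evaluation
    workflow runs end-to-end without external data, plus plain-text raster
    and occurrence-table input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
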