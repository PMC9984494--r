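Package: cropextremes
Title: Compound Hot-Dry and Cold-Wet Growing-Season Extremes and Crop Yield Anomalies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying how co-occurring hot-dry
    (and cold-wet) weather extremes during the crop growing season relate to
    annual crop yield anomalies, and how the probability of such compound
    events has changed over time. Builds growing-season climate indicators
    from gridded daily weather (sub-daily sine-interpolated temperature,
    soil-moisture deficit, histogram binning, percentile-based extreme-day
    counts), de-trends yields with a five-year moving average, fits
    year-blocked out-of-sample gradient-boosted tree regressions with
    randomized hyperparameter search and repeated resampling, estimates
    yield responses to sigma-scaled extreme scenarios via partial
    dependence, and fits logistic trends in compound-event probability with
    a triple significance gate. Ships a synthetic gridded-data generator
    with known ground-truth effect sizes so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
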