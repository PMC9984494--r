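# cropextremes

Quantifying how co-occurring hot-dry (and cold-wet) growing-season weather
extremes relate to annual crop yield anomalies, and how the probability of
such compound seasons has changed over time.

The package is written for agro-climatologists and biostatisticians who
work with gridded daily weather (temperature, precipitation, soil
moisture), crop calendars and annual yield panels. It implements the full
analysis chain as composable, tested R functions plus a one-call pipeline,
and ships a synthetic gridded-data generator with known ground-truth
effect sizes so the entire chain can be validated without any external
data.

## The method in brief

**Indicators.** For each grid cell and season year, the 90 days ending at
harvest are summarised into histograms of sub-daily temperature (sine
interpolation between *T*<sub>min</sub> and *T*<sub>max</sub>, 24
samples/day, 0.1 °C bins) and daily soil-moisture deficit
((max − sm)/(max − min), 0.001 bins), merged across irrigated and rainfed
calendars with harvested-area weights. Pooling all years of a cell,
extreme-day counts are days beyond the pooled percentiles:

> hot days = days with *T* above the cell's 90th percentile, dry days =
> days with deficit above the 90th percentile; cold/wet analogously below
> the 10th.

**Yield anomalies.** Per cell, `(y − MA₅(y)) / MA₅(y)` — proportional
deviations from a centred five-year moving average.

**Yield model.** Extreme-day counts (dry/wet square-root transformed) and
linearly de-trended average conditions, all z-scored per cell, feed a
gradient-boosted tree regression (≤ 400 trees, depth 3) fitted under a
year-blocked protocol: years are split into four groups; each group is
predicted strictly out of sample by a model trained on two of the others
with the third monitoring early stopping (patience 40), after a randomized
hyperparameter search (5 candidates, year-wise 3-fold CV). Skill is the
sign-preserved squared Pearson correlation *sign(r)·r²* between reported
and predicted anomalies aggregated to yearly, area-weighted means; the
whole procedure is repeated (default 10×, re-randomizing the year split)
for uncertainty.

**Scenario impacts.** Partial dependence: fix the standardized hot/dry (or
cold/wet) day-count features at σ levels (e.g. both at 1.5 σ) over a
random background sample of 1000 observations and average the model
output, per fold and repeat → mean impact in % yield anomaly with a
2.5–97.5 percentile interval. Mapped estimates whose 95% interval covers
zero are set to zero.

**Probability trends.** A cell-year is compound hot-dry if both
standardized day-count anomalies are ≥ 1.5 σ. With every cell-year as an
observation, logit *P*(event) = α + β·(year − ȳ); the per-year odds ratio
is e^β. A trend is reported only if the likelihood-ratio test, the
two-tailed t-test on β, and a 100-resample bootstrap all give *p* < 0.05;
otherwise the reported odds ratio is gated to 1.

## Worked example

The default desk-scale configuration simulates 50 cells × 30 years in
which compound hot-dry seasons carry a 10% yield penalty and their
log-odds rise by 0.0555/year from a 2% starting probability:

```r
library(cropextremes)
cfg <- default_config(seed = 7)
res <- run_pipeline(cfg, "readme_run")

summary(res$fit$r2_global)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.094   0.098   0.123   0.122   0.131   0.177

res$scenarios
#>      kind level_sigma mean_pct ci_lower ci_upper mapped_pct n_repeats
#>   hot-dry         1.5    -0.34    -0.67    -0.17      -0.34        10
#>  cold-wet         1.5     0.03    -0.10     0.13       0.00        10
#>       hot         1.5    -0.05    -0.24     0.05       0.00        10
#>       dry         1.5    -0.25    -0.35    -0.11      -0.25        10
#>      cold         1.5     0.06    -0.02     0.11       0.00        10
#>       wet         1.5    -0.01    -0.08     0.07       0.00        10

res$trends
#>    unit     pair   slope odds_ratio  p_lrt    p_t p_boot significant reported_or
#>  global  hot-dry  0.0386      1.039 0.0059 0.0068   0.02        TRUE       1.039
#>  global cold-wet -0.0260      0.974 0.6300 0.6300   0.28       FALSE       1.000
```

Reading the output: the model explains ~12% of the yearly aggregated
anomaly variance in this rare-event world; the compound hot-dry scenario
at 1.5 σ reduces yields (−0.34%, interval excluding zero) and dominates
both single extremes, while cold-wet and single-extreme scenarios whose
intervals cover zero are mapped to 0. The hot-dry event probability rises
significantly (odds ratio 1.039/year, all three gates < 0.05), whereas the
cold-wet trend fails the gate and is reported as 1 (no trend). All
artifacts (indicator, feature, prediction, scenario and trend tables, plus
a JSONL run log) are written to `readme_run/`, stamped with the
configuration hash.

With more cells and a higher event rate (the generator defaults used in
the scripts below) the same pipeline recovers substantially stronger
signals; see the methods vignette
(`vignettes/compound-extremes-methods.Rmd`) for the generator design, all
tunable parameters, and known limitations.

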