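---
title: "Methods: compound growing-season extremes and crop yield anomalies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound growing-season extremes and crop yield anomalies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropextremes)
```

## The problem

Co-occurring hot and dry (and, symmetrically, cold and wet) conditions
during the growing season stress crops more than either condition alone,
and the frequency of such compound seasons appears to be changing.
`cropextremes` implements a complete, testable pipeline for quantifying
both questions on gridded daily weather and annual yield data:

1. engineer growing-season climate indicators from daily weather and crop
   calendars;
2. model yield anomalies with repeated, year-blocked, strictly
   out-of-sample gradient-boosted tree regressions;
3. estimate yield responses to sigma-scaled extreme scenarios via partial
   dependence with resampled confidence intervals;
4. fit logistic trends in the probability of compound events with a
   conservative triple significance gate.

Because the real-world inputs of such studies (multi-decade reanalysis
weather, sub-national yield statistics, crop calendars) are large and
access-restricted, the package ships a synthetic gridded world with known
ground-truth effect sizes. Every stage is validated against that truth or
against independent oracles in the test suite.

## The synthetic world

`synth_config()` defines a small grid observed daily over `n_years`
(default 30) years of 365 days.

* **Temperature.** Daily mean temperature is a per-cell sinusoidal
  seasonal cycle (amplitude 8 degC around per-cell baselines spanning
  12-28 degC) plus iid Gaussian daily anomalies (sd 3 degC). `tmin` and
  `tmax` sit a fixed diurnal range (10 degC) below/above the mean.
* **Soil moisture.** A clipped Gaussian (mean 0.30, sd 0.05 m3/m3) whose
  daily anomaly is coupled to the temperature anomaly through a bivariate
  normal with correlation -0.6: hot days tend to be dry days, as in real
  land-atmosphere coupling.
* **Precipitation.** iid gamma (mean 2.5 mm/day, shape 0.5), giving the
  skewed, intermittent daily totals the precipitation indicators need.
  Precipitation carries no yield signal in the synthetic truth; it serves
  as a realistic nuisance feature.
* **Calendars.** Rainfed harvest dates are drawn per cell; irrigated
  harvests lead by a configurable 15-day lag; regime area fractions sum to
  one per cell, and one cell always harvests early enough that its 90-day
  pre-harvest window crosses the calendar-year boundary, exercising the
  wrap-around code path.
* **Compound seasons.** Each (cell, year) draws a latent Bernoulli flag
  whose log-odds are linear in year:
  `logit P(flag) = logit(p0) + beta * (year - 1) + u_year`. Flagged
  seasons have the pre-harvest window shifted hot (+1.5 anomaly sd) and
  dry (-1.5 sd), and receive a multiplicative yield penalty. The linear
  log-odds make the generative trend an exact closed-form target for the
  trend-recovery tests. An alternative design — drifting the joint
  anomaly mean continuously in year — was rejected because the implied
  joint-exceedance probability is not logistic in year, so no closed-form
  recovery target would exist.
* **Yields.** `yield = yield_base * (1 + management_trend)^(year-1) *
  (1 - penalty * flag) * (1 + noise)`, with default penalty 0.10, noise sd
  0.03 and a 1%/year management trend. The penalty applies if and only if
  the latent flag is set, so event-conditional yield effects are known
  exactly.

Two defaults deserve justification because downstream validation depends
on them:

* `hotdry_base_prob = 0.10`. Real compound events coded at a joint
  1.5-sigma threshold are rarer, but real studies aggregate over tens of
  thousands of grid cells; at the package's desk scales (tens to hundreds
  of cells) the same per-event effect would drown in yield noise. The
  rate is chosen so that the weather-explained share of aggregated yield
  variance in the synthetic world falls in the 25-50% range reported for
  major crops, making the validation suite informative at desk scale.
* `hotdry_year_sd = 0.5`. A shared yearly random effect on the event
  log-odds emulates the spatial coherence of interannual climate
  variability (continental drought years). Without it, year-to-year
  variation in global event prevalence is purely binomial and the yearly
  aggregated weather signal is seed-lottery noise. Trend-recovery and
  type-I-error tests set it to zero explicitly, because their target is
  the pure independent-Bernoulli logistic model.

A master seed spawns labelled substreams (`substream_seed()`) for weather,
precipitation, flags, yield noise, calendars, model splits and bootstrap
resampling, so stages can be regenerated independently and runs are
bit-reproducible.

What the generator does *not* emulate: spatial correlation of weather
between cells beyond the shared year effect, day-to-day autocorrelation,
multiple cropping seasons, irrigation feedback on soil moisture, or any
lat/lon physics. Passing tests therefore demonstrate that the pipeline
recovers known effects from data with this statistical structure — not
that real data meet these assumptions.

## Growing-season indicators

For each cell, regime and season year the 90 days ending at harvest (the
stress-sensitive pre-harvest period; configurable, including full-season)
are reduced to histograms:

* **Sub-daily temperature.** The daily temperature course is approximated
  by a sine with mean `(tmin+tmax)/2` and amplitude `(tmax-tmin)/2`,
  sampled 24 times per day (hourly granularity, matching the cadence of
  typical soil-moisture sources; the sample count is configurable).
  Samples are binned at 0.1 degC from -20 to 60 degC.
* **Soil-moisture deficit.** Daily soil moisture is mapped to
  `(max - sm) / (max - min)` with the reference range taken per grid cell
  over the full record (soil properties vary across space, so a global
  range would compress the dynamic range of wet regions). Deficit is
  binned at 0.001 from 0 to 1.

Bins are half-open `[lower, upper)` with the final bin closed; values
outside the global range clamp into the terminal bins, so histograms are
total-preserving. Temperature counts are divided by the samples-per-day so
both histograms integrate to the season length in days. Irrigated and
rainfed histograms are merged bin-wise with harvested-area weights.

**Extreme-day counts.** For each cell the within-season days are pooled
across all years and the 90th (hot, dry) and 10th (cold, wet) percentiles
of the pooled binned distribution define that cell's thresholds; extreme
days per season are the day mass beyond the threshold. Because a
percentile generally falls inside a bin, the threshold carries the
fraction of the bin's pooled mass below the percentile point and counting
splits the threshold bin proportionally (the standard interpolated
histogram percentile). This choice makes the histogram path agree with
percentiles computed on the raw un-binned values to sub-bin accuracy and
calibrates the all-years mean count to exactly 10% of the season length;
a strict all-or-nothing treatment of the threshold bin was tried first
and produced occasional multi-day discrepancies against the raw-series
oracle when several days of one season share a bin.

Average conditions (mean temperature, mean soil moisture, season
precipitation, and precipitation over the 365 days preceding harvest) are
computed per regime and area-weighted. Season years whose growing-season
or annual-precipitation window would precede the record start are
dropped, so a 30-year record yields 29 usable seasons.

## Model-ready features

* **Yield anomalies.** Per cell, a centred five-year moving average is
  subtracted from annual yields and the difference divided by the same
  average: proportional deviations from normal conditions. The first/last
  two years use a truncated centred window so all years remain usable.
  Anomalies are invariant to rescaling a cell's yields; cells with
  non-positive baselines are excluded.
* **Standardisation.** All climate variables are z-scored per cell across
  years (the event threshold is about deviation from the *local*
  long-term average). The population (divisor n) standard deviation is
  used and documented because the 1.5-sigma event coding inherits it.
  Dry- and wet-day counts are square-root transformed first to even out
  their skew. The four average-condition variables are linearly de-trended
  (OLS on year) before z-scoring; the extreme-day counts are not, unless
  the sensitivity flag `detrend_extremes` is set. Constant columns map to
  zeros.
* **Climate bins.** Cells are divided into quintiles of climatological
  (all-years mean) growing-season temperature, and each temperature
  quintile into quintiles of annual precipitation computed within that
  quintile, giving 25 zones of near-equal size. Ties break by cell id, so
  the assignment is deterministic and order-invariant.

## The yield model

The fitting protocol, per repeat (default 10 at desk scale; 100 for
full-scale uncertainty):

1. Years are randomly dealt into four near-equal groups. Each group in
   turn is the held-out prediction set; of the remaining three, two train
   and one (rotating) monitors early stopping. Blocking whole years
   prevents leakage through shared weather within a year.
2. Before each fold's final fit, five hyperparameter candidates are drawn
   uniformly from the boxes: row subsample and per-tree feature fraction
   in [0.5, 1], L2 penalty in [0.5, 1.5], split-gain penalty in
   [0, 0.05]. The winner has the lowest mean RMSE under threefold
   cross-validation whose folds hold disjoint years; ties go to the first
   candidate drawn.
3. The fold model is a gradient-boosted tree ensemble (squared-error
   objective, at most 400 trees of depth 3, learning rate 0.1). Boosting
   halts after 40 rounds without improvement of the evaluation RMSE and
   the best-round model is kept. The patience interpretation (40 rounds
   without a new best, rather than 40 strictly consecutive increases) is
   deliberate: with stochastic subsampling a strictly monotone error
   increase is nearly unreachable, which would disable stopping entirely.
4. Held-out predictions from the four folds assemble a continuous
   out-of-sample anomaly series per cell.

Explained variance is reported as the squared Pearson correlation, sign
preserved, between reported and predicted anomalies aggregated to one
value per year by a harvested-area-weighted mean. The spread of this
statistic across repeats (2.5-97.5 percentiles) is the repeat-uncertainty
interval. Feature attribution uses additive tree-SHAP contributions
(which reconstruct each prediction exactly), summarised as the mean
absolute contribution per feature across all fold models and repeats.

## Scenario impacts

Partial dependence fixes the standardised extreme-day columns at chosen
sigma values over a random background sample of 1000 observations (drawn
without replacement, fresh per repeat, seeded) and averages the model
output, expressed in percent yield anomaly. Because the features are
z-scores, sigma units are native; for dry/wet days the injection happens
in the final (square-root-then-z-scored) column, i.e. the modelled
feature itself. Per repeat the four fold models are averaged, and the
repeat distribution gives the mean and 95% interval. Mapped per-bin
estimates are set to zero when zero lies inside the interval.

A property to keep in mind when reading scenario values: the partial
dependence at exactly (1.5, 1.5) sigma is a *conservative* estimate of
the event-conditional yield effect. Tree split thresholds concentrate
where data are dense, so the response at the 1.5-sigma boundary is
attenuated relative to the deep event region, and fixing only the two
extreme-day columns leaves correlated co-features (season means, which
also shift in genuinely compound seasons) at background values. The test
suite therefore validates scenario estimates by sign, by compound
dominance over single extremes, by monotonicity in the planted penalty
and by null coverage — not by equating the boundary value with the raw
event-conditional anomaly, which it systematically understates.

## Trends in compound-event probability

A cell-year is a compound hot-dry (cold-wet) event when both constituent
standardised day-count anomalies are at least 1.5 sigma (inclusive).
Treating each cell-year as an observation, the event indicator is
regressed on the year (centred at the series midpoint; centring affects
only the intercept) by maximum-likelihood logistic regression. The
per-year odds ratio is `exp(slope)`.

Significance is triple-gated; the trend counts only if all three
p-values fall below 0.05:

* likelihood-ratio test against the intercept-only model;
* two-tailed t-test on the slope (Wald statistic with residual degrees of
  freedom; numerically indistinguishable from the z-test at these sample
  sizes);
* a nonparametric bootstrap (100 resamples of the observations): the
  two-sided fraction of resampled slopes crossing zero, with a +1/(N+1)
  continuity correction so p is never exactly zero at finite N.

Reported odds ratios are gated to 1 when the triple test fails, and
complete separation is detected and reported as no trend. Companion
outputs are the fitted probability curve with the empirical annual event
fraction and its five-year moving average, a bootstrap envelope of
refitted curves, and a linearity check: years are split into five
contiguous blocks and each block's empirical event fraction is mapped to
log-odds (with a 0.5 continuity correction on zero-event blocks); under
a linear-in-log-odds trend the block values are collinear with the block
midpoints.

## Numerical and reproducibility choices

* Population-sd z-scores; constant columns to zero with a warning.
* Quintile and split ties break by stable id order.
* Histogram bin edges half-open, terminal bins clamp.
* Boosted-tree internal subsampling is seeded from the repeat substream,
  so entire runs are bit-reproducible; artifact tables are written with
  17 significant digits so they round-trip exactly, and each carries the
  hash of the scientific configuration (stage toggles excluded) so mixing
  artifacts across configurations is detected.
* Desk-scale defaults: 50-200 cells, 30 years, 10 repeats, 100 bootstrap
  resamples. The test suite uses 20-300 cells; the result-reproduction
  script uses 100 cells (impact study) and 200 cells (trend study). The
  full-scale protocol (100 repeats) is one config key away.

## Known limitations

* Yearly aggregated explained variance at a few hundred cells is
  dominated by the shared-year component of event prevalence; its
  absolute value is a property of the synthetic world, not a forecast of
  real-data performance.
* Partial dependence at threshold sigma levels understates deep-event
  effects (see above).
* With the yearly random effect active, binomial-likelihood p-values for
  the trend are anticonservative with respect to the year-clustered
  generative process; the bootstrap gate resamples observations, not
  years, and shares this property. This mirrors the standard analysis
  design, which treats cell-years as exchangeable observations.
* The logistic trend model assumes linear log-odds; the quintile
  linearity check is diagnostic, not inferential.
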