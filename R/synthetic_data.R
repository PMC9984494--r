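#' Configuration for the synthetic gridded crop-climate world
#'
#' Defines a small gridded world with a seasonal temperature cycle,
#' temperature-coupled soil moisture, crop calendars with irrigated and
#' rainfed variants, and yields that carry a known multiplicative penalty in
#' seasons flagged as compound hot-dry. Every downstream stage of the
#' pipeline (indicator engineering, boosted-tree fitting, partial-dependence
#' scenarios, logistic trend estimation) can therefore be validated against
#' ground truth.
#'
#' Compound hot-dry seasons are planted explicitly: each (cell, year) draws
#' a latent Bernoulli flag whose log-odds rise linearly in year at
#' `hotdry_trend_logodds_per_year`, and flagged seasons have their daily
#' temperature anomalies shifted up and soil moisture shifted down across
#' the pre-harvest window. The logistic slope of the flag process is
#' therefore an exact closed-form target for trend recovery.
#'
#' @param n_cells number of grid cells.
#' @param n_years number of years (>= 10; moving-average de-trending needs a
#'   window).
#' @param days_per_year days per model year (365; no leap days).
#' @param season_length_days length of the pre-harvest growing-season window
#'   used downstream (days).
#' @param base_temp_by_cell per-cell annual mean temperature (degC); default
#'   an even gradient from 12 to 28 degC.
#' @param seasonal_amplitude amplitude of the sinusoidal seasonal temperature
#'   cycle (degC).
#' @param temp_sd sd of the daily temperature anomaly (degC).
#' @param diurnal_range fixed tmax - tmin spread around the daily mean (degC).
#' @param sm_mean,sm_sd mean and sd of daily volumetric soil moisture
#'   (m3/m3); values are clipped to `[0, 1]`.
#' @param temp_sm_corr correlation between daily temperature and soil
#'   moisture anomalies, in `[-1, 0]` (hot days tend to be dry days).
#' @param precip_mean mean daily precipitation (mm/day).
#' @param precip_shape gamma shape of daily precipitation (skewed,
#'   intermittent-like rain for shape < 1).
#' @param hotdry_base_prob probability that a season is compound hot-dry in
#'   year 1.
#' @param hotdry_trend_logodds_per_year linear trend in the log-odds of a
#'   compound hot-dry season, per year (0 = stationary climate).
#' @param hotdry_year_sd sd of a shared yearly random effect on the event
#'   log-odds, emulating the spatial coherence of interannual climate
#'   variability (continental drought years). Set to 0 for the pure
#'   independent-Bernoulli logistic model with a closed-form trend target.
#' @param hotdry_shift_temp,hotdry_shift_sm size of the within-season shift
#'   applied to flagged seasons, in units of `temp_sd` / `sm_sd`.
#' @param calendar_lag_days offset (days) between irrigated and rainfed
#'   harvest dates.
#' @param growing_duration_days planting-to-harvest duration (days).
#' @param yield_base baseline yield (t/ha).
#' @param hotdry_penalty multiplicative yield penalty in flagged seasons
#'   (fraction in `[0, 1)`).
#' @param yield_noise_sd sd of multiplicative iid yield noise (fraction).
#' @param management_trend multiplicative yield trend per year (fraction),
#'   emulating slowly improving management.
#' @param seed master seed; all stages derive substream seeds from it.
#' @return a `synth_config` list with validated fields.
#' @export
synth_config <- function(n_cells = 50,
                         n_years = 30,
                         days_per_year = 365,
                         season_length_days = 90,
                         base_temp_by_cell = NULL,
                         seasonal_amplitude = 8,
                         temp_sd = 3,
                         diurnal_range = 10,
                         sm_mean = 0.30,
                         sm_sd = 0.05,
                         temp_sm_corr = -0.6,
                         precip_mean = 2.5,
                         precip_shape = 0.5,
                         hotdry_base_prob = 0.10,
                         hotdry_trend_logodds_per_year = 0,
                         hotdry_year_sd = 0.5,
                         hotdry_shift_temp = 1.5,
                         hotdry_shift_sm = 1.5,
                         calendar_lag_days = 15,
                         growing_duration_days = 150,
                         yield_base = 4,
                         hotdry_penalty = 0.10,
                         yield_noise_sd = 0.03,
                         management_trend = 0.01,
                         seed = 1L) {
  if (n_cells < 1 || n_years < 10 || days_per_year < 1)
    stop("non-positive dimensions or fewer than 10 years")
  if (season_length_days >= days_per_year)
    stop("season_length_days must be shorter than the year")
  if (temp_sm_corr < -1 || temp_sm_corr > 0)
    stop("temp_sm_corr must lie in [-1, 0]")
  if (hotdry_penalty < 0 || hotdry_penalty >= 1)
    stop("hotdry_penalty must lie in [0, 1)")
  if (hotdry_base_prob < 0 || hotdry_base_prob >= 1)
    stop("hotdry_base_prob must lie in [0, 1)")
  if (is.null(base_temp_by_cell))
    base_temp_by_cell <- seq(12, 28, length.out = n_cells)
  if (length(base_temp_by_cell) != n_cells)
    stop("base_temp_by_cell must have one entry per cell")
  cfg <- list(
    n_cells = as.integer(n_cells), n_years = as.integer(n_years),
    days_per_year = as.integer(days_per_year),
    season_length_days = as.integer(season_length_days),
    base_temp_by_cell = as.numeric(base_temp_by_cell),
    seasonal_amplitude = seasonal_amplitude, temp_sd = temp_sd,
    diurnal_range = diurnal_range,
    sm_mean = sm_mean, sm_sd = sm_sd, temp_sm_corr = temp_sm_corr,
    precip_mean = precip_mean, precip_shape = precip_shape,
    hotdry_base_prob = hotdry_base_prob,
    hotdry_trend_logodds_per_year = hotdry_trend_logodds_per_year,
    hotdry_year_sd = hotdry_year_sd,
    hotdry_shift_temp = hotdry_shift_temp, hotdry_shift_sm = hotdry_shift_sm,
    calendar_lag_days = as.integer(calendar_lag_days),
    growing_duration_days = as.integer(growing_duration_days),
    yield_base = yield_base, hotdry_penalty = hotdry_penalty,
    yield_noise_sd = yield_noise_sd, management_trend = management_trend,
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Generate crop calendars with irrigated and rainfed variants
#'
#' Rainfed harvest day-of-year is drawn per cell; the irrigated harvest is
#' offset by `calendar_lag_days`. Cell 1 always harvests early in the year so
#' that at least one pre-harvest window crosses the year boundary (a code
#' path the indicator stage must handle). Per-cell irrigated/rainfed area
#' fractions sum to one; `area_total` is a per-cell harvested-area weight
#' used for area-weighted aggregation.
#'
#' @param config a [synth_config()].
#' @return a `crop_calendar` data frame with columns cell, regime,
#'   planting_doy, harvest_doy, area_frac, area_total.
#' @export
generate_calendar <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "calendar"))
  n <- config$n_cells
  dpy <- config$days_per_year
  harvest_rf <- sample(seq.int(max(2L, round(dpy / 3)), round(dpy * 0.9)),
                       n, replace = TRUE)
  # cell 1 harvests early so its pre-harvest window wraps the year boundary
  harvest_rf[1] <- max(2L, round(dpy / 6))
  lag <- config$calendar_lag_days
  harvest_irr <- ((harvest_rf - lag - 1L) %% dpy) + 1L
  plant <- function(h) ((h - config$growing_duration_days - 1L) %% dpy) + 1L
  frac_irr <- round(stats::runif(n, 0.05, 0.95), 6)
  area_total <- exp(stats::rnorm(n, 0, 0.5))
  cal <- data.frame(
    cell = rep(seq_len(n), times = 2L),
    regime = rep(c("irrigated", "rainfed"), each = n),
    planting_doy = c(plant(harvest_irr), plant(harvest_rf)),
    harvest_doy = c(harvest_irr, harvest_rf),
    area_frac = c(frac_irr, 1 - frac_irr),
    area_total = rep(area_total, times = 2L))
  class(cal) <- c("crop_calendar", "data.frame")
  cal
}

#' Draw the latent compound hot-dry season flags
#'
#' Each (cell, year) is flagged compound hot-dry with probability
#' `plogis(qlogis(hotdry_base_prob) + slope * (year - 1))`, where the slope
#' is `hotdry_trend_logodds_per_year`. The flags are the generative ground
#' truth: flagged seasons receive the within-season weather shift and the
#' multiplicative yield penalty, and the slope is the closed-form target for
#' logistic trend recovery.
#'
#' @param config a [synth_config()].
#' @return a `synthetic_truth` list: `flags` (n_cells x n_years logical
#'   matrix), `prob_by_year`, `slope_logodds_per_year`,
#'   `intercept_logodds` (year-1 log-odds).
#' @export
generate_truth_flags <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "flags"))
  year_effect <- stats::rnorm(config$n_years, 0, config$hotdry_year_sd)
  intercept <- stats::qlogis(max(config$hotdry_base_prob, 1e-12))
  p_year <- stats::plogis(intercept +
    config$hotdry_trend_logodds_per_year * (seq_len(config$n_years) - 1L) +
    year_effect)
  if (config$hotdry_base_prob == 0) p_year[] <- 0
  flags <- matrix(
    stats::runif(config$n_cells * config$n_years) <
      rep(p_year, each = config$n_cells),
    nrow = config$n_cells)
  out <- list(flags = flags, prob_by_year = p_year,
              slope_logodds_per_year = config$hotdry_trend_logodds_per_year,
              intercept_logodds = intercept)
  class(out) <- "synthetic_truth"
  out
}

#' Generate the daily weather cube
#'
#' Temperature follows a per-cell sinusoidal seasonal cycle plus iid Gaussian
#' daily anomalies; soil moisture is a clipped Gaussian whose daily anomaly
#' is coupled to the temperature anomaly through a bivariate normal with
#' correlation `temp_sm_corr`. Daily precipitation is iid gamma. In seasons
#' flagged compound hot-dry, the pre-harvest window (union of the irrigated
#' and rainfed windows) is shifted hot and dry by `hotdry_shift_temp` /
#' `hotdry_shift_sm` anomaly sds.
#'
#' @param config a [synth_config()].
#' @param calendar optional [generate_calendar()] result; generated from the
#'   config if missing.
#' @param truth optional [generate_truth_flags()] result; generated from the
#'   config if missing.
#' @return a `weather_cube`: matrices (n_cells x n_days) `tmin`, `tmax`,
#'   `tmean`, `precip`, `sm`, plus dimensions.
#' @export
generate_weather <- function(config, calendar = NULL, truth = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(calendar)) calendar <- generate_calendar(config)
  if (is.null(truth)) truth <- generate_truth_flags(config)
  n <- config$n_cells
  dpy <- config$days_per_year
  nd <- dpy * config$n_years
  doy <- rep(seq_len(dpy), times = config$n_years)
  seasonal <- outer(config$base_temp_by_cell, rep(1, nd)) +
    config$seasonal_amplitude *
      matrix(sin(2 * pi * (doy - 120) / dpy), n, nd, byrow = TRUE)

  set.seed(substream_seed(config$seed, "weather"))
  z1 <- matrix(stats::rnorm(n * nd), n, nd)
  z2 <- matrix(stats::rnorm(n * nd), n, nd)
  rho <- config$temp_sm_corr
  eps_t <- z1
  eps_s <- rho * z1 + sqrt(1 - rho^2) * z2

  tmean <- seasonal + config$temp_sd * eps_t
  sm <- config$sm_mean + config$sm_sd * eps_s

  # plant the compound hot-dry seasons
  windows <- season_windows_by_regime(calendar, config$season_length_days,
                                      dpy, config$n_years)
  for (cell in seq_len(n)) {
    for (yr in which(truth$flags[cell, ])) {
      idx <- flagged_day_indices(windows, cell, yr)
      if (length(idx)) {
        tmean[cell, idx] <- tmean[cell, idx] +
          config$hotdry_shift_temp * config$temp_sd
        sm[cell, idx] <- sm[cell, idx] -
          config$hotdry_shift_sm * config$sm_sd
      }
    }
  }
  sm[sm < 0] <- 0
  sm[sm > 1] <- 1

  set.seed(substream_seed(config$seed, "precip"))
  precip <- matrix(
    stats::rgamma(n * nd, shape = config$precip_shape,
                  scale = config$precip_mean / config$precip_shape),
    n, nd)

  cube <- list(
    tmin = tmean - config$diurnal_range / 2,
    tmax = tmean + config$diurnal_range / 2,
    tmean = tmean, precip = precip, sm = sm,
    n_cells = n, n_years = config$n_years, days_per_year = dpy)
  class(cube) <- "weather_cube"
  cube
}

# absolute day-index windows per (cell, regime, year); entries NULL when the
# window would precede the record start
season_windows_by_regime <- function(calendar, window_days, days_per_year,
                                     n_years) {
  lapply(split(calendar, calendar$regime), function(cal) {
    cal <- cal[order(cal$cell), ]
    lapply(seq_len(nrow(cal)), function(i) {
      lapply(seq_len(n_years), function(yr) {
        extract_season_window(cal$harvest_doy[i], yr, window_days,
                              days_per_year, strict = FALSE)
      })
    })
  })
}

flagged_day_indices <- function(windows, cell, yr) {
  idx <- unlist(lapply(windows, function(reg) reg[[cell]][[yr]]))
  unique(idx[idx >= 1])
}

#' Generate the yield panel from latent flags
#'
#' Yield for cell c in year y is
#' `yield_base * (1 + management_trend)^(y-1) * (1 - hotdry_penalty * flag) *
#' (1 + noise)`, with iid Gaussian multiplicative noise of sd
#' `yield_noise_sd`. The penalty is applied if and only if the season's
#' latent compound hot-dry flag is set.
#'
#' @param truth a [generate_truth_flags()] result.
#' @param config a [synth_config()].
#' @return a `yield_panel` data frame with columns cell, year, yield (t/ha).
#' @export
generate_yields <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "synthetic_truth"))
  set.seed(substream_seed(config$seed, "yield_noise"))
  n <- config$n_cells
  ny <- config$n_years
  noise <- matrix(stats::rnorm(n * ny, 0, config$yield_noise_sd), n, ny)
  trend <- (1 + config$management_trend)^(col(noise) - 1L)
  y <- config$yield_base * trend *
    (1 - config$hotdry_penalty * truth$flags) * (1 + noise)
  out <- data.frame(cell = rep(seq_len(n), times = ny),
                    year = rep(seq_len(ny), each = n),
                    yield = as.vector(y))
  out <- out[order(out$cell, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("yield_panel", "data.frame")
  out
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper running [generate_calendar()],
#' [generate_truth_flags()], [generate_weather()] and [generate_yields()]
#' with consistent substreams of the master seed.
#'
#' @param config a [synth_config()].
#' @return list with `config`, `calendar`, `truth`, `weather`, `yields`.
#' @export
generate_dataset <- function(config) {
  calendar <- generate_calendar(config)
  truth <- generate_truth_flags(config)
  weather <- generate_weather(config, calendar, truth)
  yields <- generate_yields(truth, config)
  list(config = config, calendar = calendar, truth = truth,
       weather = weather, yields = yields)
}
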