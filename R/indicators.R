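#' Sub-daily temperature samples from a sine-shaped diurnal cycle
#'
#' The daily temperature distribution is approximated by a sine curve with
#' mean `(tmin + tmax) / 2` and amplitude `(tmax - tmin) / 2`, sampled at
#' `samples_per_day` equally spaced phases over one full period. Samples are
#' therefore always within `[tmin, tmax]` and their mean converges to the
#' daily midpoint as the sampling density grows.
#'
#' @param tmin,tmax daily minimum/maximum temperature (degC); vectors of
#'   equal length (one entry per day).
#' @param samples_per_day number of equally spaced samples per day.
#' @return numeric matrix, `length(tmin)` rows x `samples_per_day` columns.
#' @export
interpolate_daily_temperature <- function(tmin, tmax, samples_per_day = 24L) {
  if (length(tmin) != length(tmax)) stop("tmin and tmax lengths differ")
  if (any(tmin > tmax)) stop("tmin exceeds tmax")
  phase <- 2 * pi * (seq_len(samples_per_day) - 1L) / samples_per_day
  mid <- (tmin + tmax) / 2
  amp <- (tmax - tmin) / 2
  mid + outer(amp, sin(phase))
}

#' Transform soil moisture into relative soil-moisture deficit
#'
#' Deficit is the rescaled complement of volumetric soil moisture:
#' `(reference_max - sm) / (reference_max - reference_min)`. Larger values
#' mean drier conditions; the reference range is the observed min/max of the
#' record (per grid cell in this implementation, since soil properties vary
#' across space).
#'
#' @param sm soil moisture series (m3/m3).
#' @param reference_min,reference_max reference range; must satisfy
#'   `reference_min < reference_max`.
#' @return deficit series in `[0, 1]` for in-range inputs.
#' @export
soil_moisture_to_deficit <- function(sm, reference_min, reference_max) {
  if (!(reference_min < reference_max)) stop("degenerate reference range")
  (reference_max - sm) / (reference_max - reference_min)
}

#' Absolute day indices of the pre-harvest growing-season window
#'
#' The window is the `window_days` consecutive days ending at harvest of the
#' given year. When harvest falls earlier in the year than the window length,
#' the window spans the year boundary into the previous calendar year. A
#' window that would precede the first day of the record is unavailable: the
#' first season of the record is dropped.
#'
#' @param harvest_doy harvest day-of-year (1-based).
#' @param year season year (1-based).
#' @param window_days window length in days.
#' @param days_per_year days per year in the record.
#' @param strict error (`TRUE`, default) or return `NULL` (`FALSE`) when the
#'   window precedes the record start.
#' @return integer vector of absolute day indices (1-based from record
#'   start), length `window_days`.
#' @export
extract_season_window <- function(harvest_doy, year, window_days = 90L,
                                  days_per_year = 365L, strict = TRUE) {
  if (harvest_doy < 1 || harvest_doy > days_per_year)
    stop("harvest day-of-year outside the calendar year")
  end <- (year - 1L) * days_per_year + as.integer(harvest_doy)
  start <- end - as.integer(window_days) + 1L
  if (start < 1L) {
    if (strict) stop("window extends before the first available day")
    return(NULL)
  }
  start:end
}

temp_bin_index <- function(x, lower = -20, upper = 60, width = 0.1) {
  n_bins <- as.integer(round((upper - lower) / width))
  i <- floor((x - lower) / width)
  i[i < 0] <- 0
  i[i >= n_bins] <- n_bins - 1L # clamp into terminal bins
  as.integer(i) + 1L
}

deficit_bin_index <- function(x, width = 0.001) {
  n_bins <- as.integer(round(1 / width))
  i <- floor(x / width)
  i[i < 0] <- 0
  i[i >= n_bins] <- n_bins - 1L
  as.integer(i) + 1L
}

#' Bin one growing season into temperature and deficit histograms
#'
#' Sub-daily sine-interpolated temperature samples are allocated to 0.1 degC
#' bins spanning -20 to 60 degC, and daily soil-moisture-deficit values to
#' 0.001-wide bins spanning 0 to 1. Bins are half-open `[lower, upper)` with
#' the final bin closed; out-of-range values clamp into the terminal bins so
#' no mass is lost. Temperature counts are expressed in day equivalents
#' (sample counts divided by `samples_per_day`), so both histograms sum to
#' the season length.
#'
#' @param weather a `weather_cube`.
#' @param cell cell index.
#' @param window absolute day indices from [extract_season_window()].
#' @param samples_per_day sub-daily sampling density for temperature.
#' @param deficit_ref optional list with `min`/`max` reference soil moisture
#'   for this cell; defaults to the cell's full-record range.
#' @return a `season_histogram`: `temp_counts` (800 bins, day equivalents),
#'   `deficit_counts` (1000 bins, days), `season_length`, `cell`.
#' @export
accumulate_histograms <- function(weather, cell, window,
                                  samples_per_day = 24L,
                                  deficit_ref = NULL) {
  stopifnot(inherits(weather, "weather_cube"))
  samples <- interpolate_daily_temperature(weather$tmin[cell, window],
                                           weather$tmax[cell, window],
                                           samples_per_day)
  tc <- tabulate(temp_bin_index(as.vector(samples)), nbins = 800L) /
    samples_per_day
  if (is.null(deficit_ref))
    deficit_ref <- list(min = min(weather$sm[cell, ]),
                        max = max(weather$sm[cell, ]))
  deficit <- soil_moisture_to_deficit(weather$sm[cell, window],
                                      deficit_ref$min, deficit_ref$max)
  dc <- tabulate(deficit_bin_index(deficit), nbins = 1000L)
  structure(list(temp_counts = tc, deficit_counts = as.numeric(dc),
                 season_length = length(window), cell = cell,
                 samples_per_day = samples_per_day),
            class = "season_histogram")
}

#' Harvested-area weighted merge of irrigated and rainfed histograms
#'
#' A grid cell can contain both irrigated and rainfed fields with different
#' growing seasons; the per-bin day counts of the two regime scenarios are
#' combined as an area-weighted average, preserving total day mass.
#'
#' @param hist_irr,hist_rf `season_histogram`s of the two regimes.
#' @param area_irr,area_rf area fractions; must sum to 1 (tolerance 1e-9).
#' @return merged `season_histogram`.
#' @export
merge_regimes <- function(hist_irr, hist_rf, area_irr, area_rf) {
  if (abs(area_irr + area_rf - 1) > 1e-9)
    stop("area weights must sum to 1")
  structure(list(
    temp_counts = area_irr * hist_irr$temp_counts +
      area_rf * hist_rf$temp_counts,
    deficit_counts = area_irr * hist_irr$deficit_counts +
      area_rf * hist_rf$deficit_counts,
    season_length = area_irr * hist_irr$season_length +
      area_rf * hist_rf$season_length,
    cell = hist_irr$cell,
    samples_per_day = hist_irr$samples_per_day),
    class = "season_histogram")
}

#' Percentile threshold of a cell's pooled seasonal distribution
#'
#' Pools the binned within-season distribution of one variable across all
#' years of a cell and locates the q-th percentile on it. On a binned
#' distribution the percentile point generally falls inside a bin, so the
#' threshold carries both the bin index and the fraction of that bin's
#' pooled mass lying below the exact percentile point. Counting then splits
#' the threshold bin proportionally (the standard interpolated-histogram
#' percentile estimator), which keeps the histogram path consistent with a
#' percentile computed on the raw pooled values to sub-bin accuracy and
#' makes the all-years total of extreme days exactly (100-q)% (or q%) of
#' the pooled day mass.
#'
#' @param histograms list of `season_histogram`s (all years of one cell).
#' @param q percentile in (0, 100), e.g. 90 for hot/dry, 10 for cold/wet.
#' @param variable `"temp"` or `"deficit"`.
#' @return a `bin_threshold`: `bin` (1-based index of the bin containing
#'   the percentile point) and `frac` (fraction of that bin's pooled mass
#'   below the point).
#' @export
percentile_threshold <- function(histograms, q,
                                 variable = c("temp", "deficit")) {
  variable <- match.arg(variable)
  field <- if (variable == "temp") "temp_counts" else "deficit_counts"
  pool <- Reduce(`+`, lapply(histograms, `[[`, field))
  total <- sum(pool)
  if (total <= 0) stop("empty pool")
  cum <- cumsum(pool)
  target <- q / 100 * total
  b <- which(cum >= target - 1e-9)[1L]
  below <- if (b > 1L) cum[b - 1L] else 0
  frac <- if (pool[b] > 0) min(1, max(0, (target - below) / pool[b])) else 1
  structure(list(bin = b, frac = frac), class = "bin_threshold")
}

#' Count growing-season days beyond a percentile threshold
#'
#' Sums the bin masses beyond the threshold in the stated direction. Mass
#' in the threshold bin itself is split at the threshold's sub-bin
#' percentile point: counting above takes the `1 - frac` share of the bin,
#' counting below the `frac` share. A plain integer threshold is accepted
#' and then treated as a strict cut at the bin's far edge (no
#' threshold-bin mass in either direction).
#'
#' @param hist a `season_histogram`.
#' @param threshold a `bin_threshold` from [percentile_threshold()], or a
#'   bare bin index.
#' @param direction `"above"` or `"below"`.
#' @param variable `"temp"` or `"deficit"`.
#' @return day count (day equivalents; fractional after regime merging and
#'   threshold-bin interpolation).
#' @export
count_extreme_days <- function(hist, threshold,
                               direction = c("above", "below"),
                               variable = c("temp", "deficit")) {
  direction <- match.arg(direction)
  variable <- match.arg(variable)
  counts <- if (variable == "temp") hist$temp_counts else hist$deficit_counts
  n <- length(counts)
  if (inherits(threshold, "bin_threshold")) {
    b <- threshold$bin
    frac <- threshold$frac
  } else {
    b <- as.integer(threshold)
    frac <- if (direction == "above") 1 else 0
  }
  if (direction == "above") {
    tail_mass <- if (b >= n) 0 else sum(counts[(b + 1L):n])
    tail_mass + counts[b] * (1 - frac)
  } else {
    tail_mass <- if (b <= 1L) 0 else sum(counts[1L:(b - 1L)])
    tail_mass + counts[b] * frac
  }
}

#' Growing-season mean conditions and precipitation totals
#'
#' Arithmetic means of daily mean temperature and soil moisture over the
#' window, total precipitation over the window, and total precipitation over
#' the 365 days ending at harvest.
#'
#' @param weather a `weather_cube`.
#' @param cell cell index.
#' @param window absolute day indices (window ends at harvest).
#' @return named list: `mean_temp`, `mean_sm`, `gs_precip`, `annual_precip`.
#' @export
season_means_and_totals <- function(weather, cell, window) {
  end <- window[length(window)]
  if (end - 364L < 1L) stop("record too short for the annual total")
  annual_idx <- (end - 364L):end
  list(mean_temp = mean(weather$tmean[cell, window]),
       mean_sm = mean(weather$sm[cell, window]),
       gs_precip = sum(weather$precip[cell, window]),
       annual_precip = sum(weather$precip[cell, annual_idx]))
}

#' Compute the growing-season indicator table
#'
#' For every cell and season year, builds regime-specific seasonal
#' histograms of sub-daily temperature and daily soil-moisture deficit,
#' merges them with harvested-area weights, derives per-cell percentile
#' thresholds from the all-years pooled distribution (90th for hot/dry,
#' 10th for cold/wet), and counts extreme days per season. Average
#' conditions (mean temperature, mean soil moisture, season and annual
#' precipitation) are computed per regime and area-weighted. Season years
#' whose growing-season window or preceding 365-day precipitation window
#' would extend before the record start are dropped.
#'
#' @param weather a `weather_cube`.
#' @param calendar a `crop_calendar`.
#' @param window_days growing-season window length (days); 90 by default
#'   (the pre-harvest period most yield-sensitive to stress).
#' @param samples_per_day sub-daily temperature sampling density.
#' @param q_upper,q_lower percentiles defining hot/dry and cold/wet days.
#' @return an `indicator_table` data frame: cell, year, hot_days, dry_days,
#'   cold_days, wet_days, mean_temp, mean_sm, gs_precip, annual_precip,
#'   area_total.
#' @export
compute_indicators <- function(weather, calendar, window_days = 90L,
                               samples_per_day = 24L,
                               q_upper = 90, q_lower = 10) {
  stopifnot(inherits(weather, "weather_cube"))
  dpy <- weather$days_per_year
  regimes <- split(calendar, calendar$regime)
  regimes <- lapply(regimes, function(d) d[order(d$cell), ])
  out <- vector("list", weather$n_cells)
  for (cell in seq_len(weather$n_cells)) {
    ref <- list(min = min(weather$sm[cell, ]), max = max(weather$sm[cell, ]))
    # a season year is usable only if both regime windows and the annual
    # precipitation window fit inside the record
    windows <- lapply(regimes, function(reg) {
      h <- reg$harvest_doy[reg$cell == cell]
      lapply(seq_len(weather$n_years), function(yr) {
        w <- extract_season_window(h, yr, window_days, dpy, strict = FALSE)
        if (!is.null(w) && (w[length(w)] - 364L) < 1L) w <- NULL
        w
      })
    })
    usable <- which(vapply(seq_len(weather$n_years), function(yr) {
      all(vapply(windows, function(reg) !is.null(reg[[yr]]), logical(1)))
    }, logical(1)))
    if (!length(usable)) next

    fracs <- vapply(regimes, function(reg) reg$area_frac[reg$cell == cell],
                    numeric(1))
    hists <- lapply(usable, function(yr) {
      hr <- lapply(names(regimes), function(rn) {
        accumulate_histograms(weather, cell, windows[[rn]][[yr]],
                              samples_per_day, deficit_ref = ref)
      })
      merge_regimes(hr[[1L]], hr[[2L]], fracs[1L], fracs[2L])
    })
    thr_hot <- percentile_threshold(hists, q_upper, "temp")
    thr_cold <- percentile_threshold(hists, q_lower, "temp")
    thr_dry <- percentile_threshold(hists, q_upper, "deficit")
    thr_wet <- percentile_threshold(hists, q_lower, "deficit")

    rows <- lapply(seq_along(usable), function(i) {
      yr <- usable[i]
      mt <- lapply(names(regimes), function(rn) {
        season_means_and_totals(weather, cell, windows[[rn]][[yr]])
      })
      wavg <- function(f) sum(fracs * vapply(mt, `[[`, numeric(1), f))
      data.frame(
        cell = cell, year = yr,
        hot_days = count_extreme_days(hists[[i]], thr_hot, "above", "temp"),
        dry_days = count_extreme_days(hists[[i]], thr_dry, "above", "deficit"),
        cold_days = count_extreme_days(hists[[i]], thr_cold, "below", "temp"),
        wet_days = count_extreme_days(hists[[i]], thr_wet, "below", "deficit"),
        mean_temp = wavg("mean_temp"), mean_sm = wavg("mean_sm"),
        gs_precip = wavg("gs_precip"), annual_precip = wavg("annual_precip"),
        area_total = regimes[[1L]]$area_total[regimes[[1L]]$cell == cell])
    })
    out[[cell]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("indicator_table", "data.frame")
  res
}
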