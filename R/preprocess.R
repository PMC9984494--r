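#' Proportional yield anomalies from a five-year moving average
#'
#' Removes slowly varying management/technology trends by subtracting a
#' centred five-year moving average from each cell's annual yields and
#' dividing by that average, giving proportional deviations from normal
#' conditions. The first and last two years use a truncated (partial)
#' centred window so every year of the record remains usable. Cells whose
#' baseline is not strictly positive in some year cannot be expressed as a
#' proportion and are excluded (recorded in the `excluded_cells` attribute).
#'
#' @param yields a `yield_panel` data frame (cell, year, yield).
#' @param window moving-average window length in years.
#' @return a `yield_anomaly_panel` data frame: cell, year, yield, baseline,
#'   anomaly.
#' @export
detrend_yield <- function(yields, window = 5L) {
  stopifnot(all(c("cell", "year", "yield") %in% names(yields)))
  pieces <- lapply(split(yields, yields$cell), function(d) {
    d <- d[order(d$year), ]
    if (nrow(d) < window) stop("fewer years than the moving-average window")
    d$baseline <- zoo::rollapply(d$yield, window, mean, partial = TRUE,
                                 align = "center")
    d
  })
  out <- do.call(rbind, pieces)
  bad <- unique(out$cell[out$baseline <= 0])
  out <- out[!(out$cell %in% bad), ]
  out$anomaly <- (out$yield - out$baseline) / out$baseline
  rownames(out) <- NULL
  attr(out, "excluded_cells") <- bad
  class(out) <- c("yield_anomaly_panel", "data.frame")
  out
}

detrend_linear <- function(x, year) {
  fit <- stats::lm.fit(cbind(1, year), x)
  as.numeric(fit$residuals)
}

#' Build the model-ready feature matrix
#'
#' Joins the indicator table with yield anomalies and standardises every
#' climate variable per cell across years (z-score with population sd, so
#' sigma-threshold event coding is expressed in the same units). Dry- and
#' wet-day counts are square-root transformed before z-scoring to even out
#' their skewed distributions. The four average-condition variables (mean
#' temperature, mean soil moisture, growing-season and annual precipitation)
#' are linearly de-trended in year before z-scoring; the extreme-day counts
#' are not de-trended in the main configuration (set `detrend_extremes` for
#' the sensitivity configuration).
#'
#' @param indicators an `indicator_table`.
#' @param anomalies a `yield_anomaly_panel`.
#' @param detrend_extremes also de-trend the extreme-day counts.
#' @param extremes_only drop the average-condition features.
#' @return a `feature_matrix` data frame: cell, year, area_total, the
#'   z-scored feature columns, and the response `yield_anom`; feature column
#'   names in attribute `feature_cols`.
#' @export
standardize_features <- function(indicators, anomalies,
                                 detrend_extremes = FALSE,
                                 extremes_only = FALSE) {
  extreme_cols <- c("hot_days", "dry_days", "cold_days", "wet_days")
  mean_cols <- c("mean_temp", "mean_sm", "gs_precip", "annual_precip")
  df <- merge(indicators,
              anomalies[, c("cell", "year", "anomaly")],
              by = c("cell", "year"))
  names(df)[names(df) == "anomaly"] <- "yield_anom"
  df <- df[order(df$cell, df$year), ]
  pieces <- lapply(split(df, df$cell), function(d) {
    for (cl in c("dry_days", "wet_days")) d[[cl]] <- sqrt(d[[cl]])
    for (cl in extreme_cols)
      if (detrend_extremes) d[[cl]] <- detrend_linear(d[[cl]], d$year)
    for (cl in mean_cols) d[[cl]] <- detrend_linear(d[[cl]], d$year)
    for (cl in c(extreme_cols, mean_cols)) d[[cl]] <- zscore(d[[cl]])
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  feature_cols <- if (extremes_only) extreme_cols else c(extreme_cols, mean_cols)
  out <- out[, c("cell", "year", "area_total", feature_cols, "yield_anom")]
  attr(out, "feature_cols") <- feature_cols
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Per-cell climatology for climate binning
#'
#' All-years mean growing-season temperature and mean annual precipitation
#' per cell, the two axes on which climate bins are defined.
#'
#' @param indicators an `indicator_table`.
#' @return data frame: cell, temp_clim, precip_clim.
#' @export
compute_climatology <- function(indicators) {
  agg <- stats::aggregate(indicators[, c("mean_temp", "annual_precip")],
                          by = list(cell = indicators$cell), FUN = mean)
  data.frame(cell = agg$cell, temp_clim = agg$mean_temp,
             precip_clim = agg$annual_precip)
}

balanced_quintile <- function(x, ids) {
  r <- order(order(x, ids)) # ranks, ties broken by stable id order
  as.integer(floor((r - 1L) * 5L / length(x)) + 1L)
}

#' Assign cells to 25 nested climate bins
#'
#' Divides cells into quintiles of climatological growing-season
#' temperature, then divides each temperature quintile into quintiles of
#' climatological annual precipitation computed from that quintile's
#' members only. The result is 25 climatologically analogous zones of
#' near-equal size (within one cell per split); ties are broken by cell id
#' so the assignment is deterministic and order-invariant.
#'
#' @param climatology data frame from [compute_climatology()].
#' @return a `bin_assignment` data frame: cell, temp_quintile,
#'   precip_quintile, bin (1..25, `bin = (temp_quintile - 1) * 5 +
#'   precip_quintile`).
#' @export
assign_climate_bins <- function(climatology) {
  if (nrow(climatology) < 25L) stop("need at least 25 cells for 25 bins")
  tq <- balanced_quintile(climatology$temp_clim, climatology$cell)
  pq <- integer(nrow(climatology))
  for (q in 1:5) {
    idx <- which(tq == q)
    pq[idx] <- balanced_quintile(climatology$precip_clim[idx],
                                 climatology$cell[idx])
  }
  out <- data.frame(cell = climatology$cell, temp_quintile = tq,
                    precip_quintile = pq, bin = (tq - 1L) * 5L + pq)
  class(out) <- c("bin_assignment", "data.frame")
  out
}
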