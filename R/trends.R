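#' Code compound (or single) extreme events from standardised anomalies
#'
#' A cell-year is a compound hot-dry (cold-wet) event when the standardised
#' anomalies of both constituent extreme-day counts are at least
#' `threshold` sigma (inclusive). Single-variable event panels use one
#' constituent only.
#'
#' @param features a `feature_matrix` with z-scored extreme-day columns.
#' @param threshold sigma threshold (1.5 in the main analysis).
#' @param pair `"hot-dry"`, `"cold-wet"`, or a single kind (`"hot"`,
#'   `"dry"`, `"cold"`, `"wet"`).
#' @return an `event_series` data frame: cell, year, event (logical), plus
#'   the underlying standardised anomaly columns.
#' @export
code_events <- function(features, threshold = 1.5, pair = "hot-dry") {
  cols <- scenario_features(pair)
  event <- Reduce(`&`, lapply(cols, function(cl) features[[cl]] >= threshold))
  out <- data.frame(cell = features$cell, year = features$year,
                    event = event, features[, cols, drop = FALSE])
  class(out) <- c("event_series", "data.frame")
  out
}

logistic_p_lrt <- function(fit) {
  stats::pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
}

boot_slope <- function(event, yc) {
  idx <- sample.int(length(event), replace = TRUE)
  f <- suppressWarnings(
    stats::glm.fit(cbind(1, yc[idx]), event[idx],
                   family = stats::binomial()))
  f$coefficients[2]
}

#' Logistic trend in compound-event probability
#'
#' Maximum-likelihood logistic regression of the event indicator on year
#' (centred at the series midpoint), treating every cell-year pair as one
#' observation. The per-year odds ratio is `exp(slope)`. Significance is
#' triple-gated: the likelihood-ratio test against the intercept-only
#' model, the two-tailed t-test on the slope, and a nonparametric bootstrap
#' over observations (`n_boot` resamples; two-sided sign-crossing fraction
#' with a +1/(N+1) continuity correction). The trend is reported as
#' significant only when all three p-values are below `alpha`, and the
#' reported odds ratio is gated to one otherwise. Complete separation is
#' flagged and reported as no trend.
#'
#' @param events an `event_series` from [code_events()].
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param alpha significance level for the triple gate.
#' @return a `trend_fit`: intercept and slope (log-odds), `odds_ratio` per
#'   year, `p_lrt`, `p_t`, `p_boot`, `significant`, `reported_or` (gated),
#'   `separation`, `year_center`, `n_events`, `n_obs`.
#' @export
fit_logistic_trend <- function(events, n_boot = 100L, seed = 1L,
                               alpha = 0.05) {
  stopifnot(inherits(events, "event_series"))
  if (length(unique(events$year)) < 2L) stop("need at least 2 distinct years")
  ne <- sum(events$event)
  if (ne == 0L || ne == nrow(events))
    stop("need at least one event and one non-event")
  ycenter <- mean(unique(events$year))
  yc <- events$year - ycenter
  fit <- suppressWarnings(
    stats::glm(events$event ~ yc, family = stats::binomial()))
  slope <- unname(stats::coef(fit)[2])
  separation <- !fit$converged || abs(slope) > 15 ||
    max(abs(stats::coef(fit))) > 50
  sm <- summary(fit)$coefficients
  p_t <- 2 * stats::pt(-abs(sm[2, "Estimate"] / sm[2, "Std. Error"]),
                       df = fit$df.residual)
  p_lrt <- logistic_p_lrt(fit)
  set.seed(substream_seed(seed, "trend_boot"))
  slopes <- vapply(seq_len(n_boot), function(i) boot_slope(events$event, yc),
                   numeric(1))
  n_opp <- sum(sign(slopes) != sign(slope))
  p_boot <- min(1, 2 * (n_opp + 1) / (n_boot + 1))
  significant <- !separation &&
    all(c(p_lrt, p_t, p_boot) < alpha, na.rm = FALSE)
  or <- exp(slope)
  structure(list(intercept = unname(stats::coef(fit)[1]), slope = slope,
                 odds_ratio = or, p_lrt = p_lrt, p_t = p_t, p_boot = p_boot,
                 significant = significant,
                 reported_or = if (significant) or else 1,
                 separation = separation, year_center = ycenter,
                 boot_slopes = slopes, n_events = ne, n_obs = nrow(events),
                 glm_fit = fit),
            class = "trend_fit")
}

#' Fitted and empirical event-probability series
#'
#' Applies the logistic inverse link to the fitted log-odds for each year
#' and reports alongside the empirical annual event fraction and its
#' centred five-year moving average.
#'
#' @param fit a `trend_fit`.
#' @param events the `event_series` the fit was computed from.
#' @return data frame: year, fitted_prob, empirical_frac, empirical_ma5.
#' @export
probability_curve <- function(fit, events) {
  stopifnot(inherits(fit, "trend_fit"))
  years <- sort(unique(events$year))
  p_fit <- stats::plogis(fit$intercept + fit$slope * (years - fit$year_center))
  frac <- vapply(years, function(y) mean(events$event[events$year == y]),
                 numeric(1))
  data.frame(year = years, fitted_prob = p_fit, empirical_frac = frac,
             empirical_ma5 = zoo::rollapply(frac, 5L, mean, partial = TRUE,
                                            align = "center"))
}

#' Bootstrap envelope of fitted probability curves
#'
#' Resamples cell-year observations with replacement, refits the logistic
#' trend on each resample, and returns the fitted probability curve per
#' resample plus the pointwise min/max envelope.
#'
#' @param events an `event_series`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list: `curves` (years x n_boot matrix of fitted probabilities),
#'   `lower`, `upper` (pointwise envelope), `years`.
#' @export
bootstrap_uncertainty_band <- function(events, n_boot = 100L, seed = 1L) {
  years <- sort(unique(events$year))
  ycenter <- mean(years)
  yc <- events$year - ycenter
  set.seed(substream_seed(seed, "trend_band"))
  curves <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(events), replace = TRUE)
    f <- suppressWarnings(
      stats::glm.fit(cbind(1, yc[idx]), events$event[idx],
                     family = stats::binomial()))
    stats::plogis(f$coefficients[1] +
                    f$coefficients[2] * (years - ycenter))
  }, numeric(length(years)))
  list(curves = curves, lower = apply(curves, 1, min),
       upper = apply(curves, 1, max), years = years)
}

#' Log-odds linearity check over temporal quintiles
#'
#' Partitions the years into five contiguous temporal blocks and maps each
#' block's empirical event fraction to the log-odds scale. Blocks with zero
#' (or all) events use a 0.5 continuity correction on the event and
#' non-event counts so the log-odds stay finite. Under a
#' linear-in-log-odds trend the block values should fall on a line against
#' the block midpoint years.
#'
#' @param events an `event_series`.
#' @return data frame: block, mid_year, n_events, n_obs, logodds.
#' @export
logodds_linearity_check <- function(events) {
  years <- sort(unique(events$year))
  if (length(years) < 5L) stop("need at least 5 distinct years")
  block_of <- stats::setNames(
    floor((seq_along(years) - 1L) * 5L / length(years)) + 1L, years)
  blk <- block_of[as.character(events$year)]
  rows <- lapply(1:5, function(b) {
    e <- sum(events$event[blk == b])
    n <- sum(blk == b)
    lo <- if (e == 0L || e == n) log((e + 0.5) / (n - e + 0.5))
          else log(e / (n - e))
    data.frame(block = b, mid_year = mean(years[block_of == b]),
               n_events = e, n_obs = n, logodds = lo)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
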