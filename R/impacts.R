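extreme_feature <- function(kind) {
  switch(kind, hot = "hot_days", dry = "dry_days", cold = "cold_days",
         wet = "wet_days", stop("unknown extreme kind: ", kind))
}

scenario_features <- function(kind) {
  switch(kind,
         "hot-dry" = c("hot_days", "dry_days"),
         "cold-wet" = c("cold_days", "wet_days"),
         extreme_feature(kind))
}

#' Partial dependence of the model output on fixed extreme anomalies
#'
#' Draws a random background sample of observations (without replacement),
#' overwrites the chosen standardised extreme-day columns with the given
#' sigma values, and returns the mean model output. Because the feature
#' columns are z-scores, sigma units are native: fixing `hot_days = 1.5`
#' means a growing season whose hot-day count sits 1.5 sd above the cell's
#' long-term average. The result is expressed in percent yield anomaly.
#'
#' @param model an `xgb.Booster`.
#' @param features a `feature_matrix` (background observations).
#' @param fixed named numeric vector: feature column -> sigma value.
#' @param sample_size background sample size (capped at the number of
#'   rows).
#' @param sample_idx optional pre-drawn row indices (overrides
#'   `sample_size`); used to share one background sample across fold
#'   models.
#' @return mean predicted yield anomaly, percent.
#' @export
partial_dependence <- function(model, features, fixed,
                               sample_size = 1000L, sample_idx = NULL) {
  fcols <- attr(features, "feature_cols")
  if (!all(names(fixed) %in% fcols))
    stop("fixed features missing from the feature matrix")
  x <- as.matrix(features[, fcols])
  if (!nrow(x)) stop("empty feature matrix")
  if (is.null(sample_idx))
    sample_idx <- sample.int(nrow(x), min(sample_size, nrow(x)))
  xs <- x[sample_idx, , drop = FALSE]
  for (nm in names(fixed)) xs[, nm] <- fixed[[nm]]
  100 * mean(predict(model, xs))
}

#' Yield-anomaly estimate for a single or compound extreme scenario
#'
#' Evaluates the partial dependence of every fold model at the given sigma
#' level of the scenario's extreme-day features, averages the four folds
#' within each repeat, and summarises the per-repeat values as a mean and a
#' 2.5-97.5 percentile confidence interval. A fresh seeded background
#' sample is drawn per repeat.
#'
#' @param fit a `cropext_fit`.
#' @param kind `"hot-dry"`, `"cold-wet"`, `"hot"`, `"dry"`, `"cold"` or
#'   `"wet"`.
#' @param level sigma level at which the scenario fixes the anomalies
#'   (1.5 in the headline analyses).
#' @param sample_size background sample size per partial-dependence call.
#' @param seed seed for the background sampling substreams.
#' @return a `scenario_estimate`: `mean`, `ci` (2.5/97.5 percentiles),
#'   per-repeat `values` (percent yield anomaly), `kind`, `level`.
#' @export
compound_scenario <- function(fit, kind = "hot-dry", level = 1.5,
                              sample_size = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "cropext_fit"))
  fixed <- stats::setNames(rep(level, length(scenario_features(kind))),
                           scenario_features(kind))
  n <- nrow(fit$features)
  values <- vapply(seq_len(fit$n_repeats), function(r) {
    set.seed(substream_seed(seed, paste0("pd", r)))
    idx <- sample.int(n, min(sample_size, n))
    mean(vapply(fit$models[[r]], function(m) {
      partial_dependence(m, fit$features, fixed, sample_idx = idx)
    }, numeric(1)))
  }, numeric(1))
  structure(list(mean = mean(values),
                 ci = stats::quantile(values, c(0.025, 0.975), names = FALSE),
                 values = values, kind = kind, level = level),
            class = "scenario_estimate")
}

#' Zero-mapping rule for mapped scenario estimates
#'
#' A mapped estimate is set to zero whenever zero lies inside its 95%
#' confidence interval; otherwise the mean is mapped.
#'
#' @param mean scenario mean.
#' @param ci length-2 confidence interval (lower, upper).
#' @return the mapped value.
#' @export
apply_zero_rule <- function(mean, ci) {
  if (ci[1] <= 0 && ci[2] >= 0) 0 else mean
}

#' Collect per-bin scenario estimates into a mapped table
#'
#' @param estimates named list of `scenario_estimate`s, one per climate bin
#'   (bins without a fitted model are simply absent).
#' @return data frame: bin, mean, ci_lower, ci_upper, mapped.
#' @export
map_bin_estimates <- function(estimates) {
  rows <- lapply(names(estimates), function(b) {
    e <- estimates[[b]]
    data.frame(bin = b, mean = e$mean, ci_lower = e$ci[1], ci_upper = e$ci[2],
               mapped = apply_zero_rule(e$mean, e$ci))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenario heatmap over a grid of paired extreme anomalies
#'
#' Evaluates the partial dependence at every point of a two-axis sigma grid
#' (default -2.25 to 2.25 in 0.25 steps, 19 levels per axis) and averages
#' across fold models and repeats. Rows index the first axis and columns
#' the second, both in ascending sigma order.
#'
#' @param fit a `cropext_fit`.
#' @param axes character pair of extreme kinds, e.g. `c("hot", "dry")`.
#' @param levels sigma levels per axis.
#' @param sample_size background sample size per repeat.
#' @param seed seed for the background sampling substreams.
#' @return numeric `length(levels) x length(levels)` matrix of mean percent
#'   yield anomalies, with sigma levels as dimnames.
#' @export
scenario_heatmap <- function(fit, axes = c("hot", "dry"),
                             levels = seq(-2.25, 2.25, by = 0.25),
                             sample_size = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "cropext_fit"), length(axes) == 2L)
  f1 <- extreme_feature(axes[1])
  f2 <- extreme_feature(axes[2])
  x <- as.matrix(fit$features[, fit$feature_cols])
  grid <- expand.grid(a = levels, b = levels)
  acc <- matrix(0, length(levels), length(levels))
  for (r in seq_len(fit$n_repeats)) {
    set.seed(substream_seed(seed, paste0("pd", r)))
    idx <- sample.int(nrow(x), min(sample_size, nrow(x)))
    xs <- x[idx, , drop = FALSE]
    # stack all grid points so each model predicts once
    big <- xs[rep(seq_len(nrow(xs)), times = nrow(grid)), , drop = FALSE]
    big[, f1] <- rep(grid$a, each = nrow(xs))
    big[, f2] <- rep(grid$b, each = nrow(xs))
    pd <- rowMeans(vapply(fit$models[[r]], function(m) {
      colMeans(matrix(predict(m, big), nrow(xs)))
    }, numeric(nrow(grid))))
    acc <- acc + 100 * matrix(pd, length(levels))
  }
  acc <- acc / fit$n_repeats
  dimnames(acc) <- list(levels, levels)
  acc
}
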