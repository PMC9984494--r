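#' Default pipeline run configuration
#'
#' Desk-scale defaults: a 50-cell, 30-year synthetic world with a 10%
#' compound hot-dry yield penalty and a rising event probability (log-odds
#' slope 0.0555/year, about a five-fold odds increase over 29 years from a
#' 2% starting probability), 90-day pre-harvest windows, 10 model repeats
#' and a 1.5-sigma event threshold. All parameters can be overridden via
#' the returned list or a YAML config file.
#'
#' @param seed master seed; every random stage derives a substream from it.
#' @return a nested `run_config` list (stages, synthetic, indicators,
#'   preprocess, model, impacts, trends, io).
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    stages = list(generate = TRUE, indicators = TRUE, preprocess = TRUE,
                  fit = TRUE, impacts = TRUE, trends = TRUE),
    synthetic = list(n_cells = 50L, n_years = 30L,
                     hotdry_penalty = 0.10, yield_noise_sd = 0.03,
                     hotdry_base_prob = 0.02,
                     hotdry_trend_logodds_per_year = 0.0555),
    indicators = list(window_days = 90L, samples_per_day = 24L,
                      q_upper = 90, q_lower = 10),
    preprocess = list(detrend_extremes = FALSE, extremes_only = FALSE,
                      yield_ma_window = 5L),
    model = list(n_repeats = 10L, n_trees = 400L, depth = 3L, eta = 0.1,
                 patience = 40L, tune_iter = 5L),
    impacts = list(level_sigma = 1.5, sample_size = 1000L,
                   kinds = c("hot-dry", "cold-wet", "hot", "dry", "cold",
                             "wet")),
    trends = list(threshold_sigma = 1.5, n_boot = 100L,
                  pairs = c("hot-dry", "cold-wet")),
    io = list(write_weather = FALSE))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save / load a run configuration as YAML
#'
#' The configuration round-trips losslessly through serialisation.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `load_run_config` returns a `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("seed")) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- c("run_config", "list")
  cfg
}

log_stage <- function(log_path, stage, n_in, n_out, seconds) {
  line <- jsonlite::toJSON(list(stage = stage, rows_in = n_in,
                                rows_out = n_out,
                                seconds = round(seconds, 3),
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           auto_unbox = TRUE)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> indicators -> preprocess -> fit -> impacts ->
#' trends on a single configuration, writing every artifact table (stamped
#' with the config hash) plus a structured run log into `outdir`. Stages
#' toggled off in `config$stages` are loaded from the artifacts of a
#' previous run in the same directory (table-producing stages) or skipped
#' (model-dependent stages).
#'
#' @param config a `run_config` from [default_config()] or
#'   [load_run_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the in-memory results of every executed
#'   stage (`dataset`, `indicators`, `features`, `bins`, `fit`,
#'   `scenarios`, `trends`).
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # the hash covers the scientific parameters only, so toggling stages or
  # io options still matches artifacts from the same analysis configuration
  hash <- config_hash(unclass(config)[setdiff(names(config),
                                              c("stages", "io"))])
  log_path <- file.path(outdir, "run_log.jsonl")
  save_run_config(config, file.path(outdir, "config.yaml"))
  res <- list(config = config, hash = hash, outdir = outdir)
  pth <- function(f) file.path(outdir, f)
  stage_on <- function(s) isTRUE(config$stages[[s]])

  # --- generate -------------------------------------------------------
  if (stage_on("generate")) {
    t0 <- proc.time()[3]
    scfg <- do.call(synth_config, c(config$synthetic, list(seed = config$seed)))
    res$dataset <- generate_dataset(scfg)
    write_artifact(res$dataset$calendar, pth("calendar.csv"), hash)
    write_artifact(res$dataset$yields, pth("yields.csv"), hash)
    if (isTRUE(config$io$write_weather))
      write_weather_csv(res$dataset$weather, pth("weather.csv"), hash)
    log_stage(log_path, "generate", 0L, nrow(res$dataset$yields),
              proc.time()[3] - t0)
  } else {
    res$dataset <- list(
      calendar = read_artifact(pth("calendar.csv"), hash),
      yields = read_artifact(pth("yields.csv"), hash))
    class(res$dataset$calendar) <- c("crop_calendar", "data.frame")
    class(res$dataset$yields) <- c("yield_panel", "data.frame")
    if (file.exists(pth("weather.csv")))
      res$dataset$weather <- read_weather_csv(pth("weather.csv"))
  }

  # --- indicators -----------------------------------------------------
  if (stage_on("indicators")) {
    t0 <- proc.time()[3]
    res$indicators <- compute_indicators(
      res$dataset$weather, res$dataset$calendar,
      window_days = config$indicators$window_days,
      samples_per_day = config$indicators$samples_per_day,
      q_upper = config$indicators$q_upper,
      q_lower = config$indicators$q_lower)
    write_artifact(res$indicators, pth("indicators.csv"), hash)
    log_stage(log_path, "indicators", nrow(res$dataset$yields),
              nrow(res$indicators), proc.time()[3] - t0)
  } else {
    res$indicators <- read_artifact(pth("indicators.csv"), hash)
    class(res$indicators) <- c("indicator_table", "data.frame")
  }

  # --- preprocess -----------------------------------------------------
  if (stage_on("preprocess")) {
    t0 <- proc.time()[3]
    anomalies <- detrend_yield(res$dataset$yields,
                               config$preprocess$yield_ma_window)
    res$features <- standardize_features(
      res$indicators, anomalies,
      detrend_extremes = config$preprocess$detrend_extremes,
      extremes_only = config$preprocess$extremes_only)
    res$bins <- assign_climate_bins(compute_climatology(res$indicators))
    write_artifact(res$features, pth("features.csv"), hash)
    write_artifact(res$bins, pth("bins.csv"), hash)
    log_stage(log_path, "preprocess", nrow(res$indicators),
              nrow(res$features), proc.time()[3] - t0)
  } else {
    res$features <- read_artifact(pth("features.csv"), hash)
    fcols <- setdiff(names(res$features),
                     c("cell", "year", "area_total", "yield_anom"))
    attr(res$features, "feature_cols") <- fcols
    class(res$features) <- c("feature_matrix", "data.frame")
    res$bins <- read_artifact(pth("bins.csv"), hash)
  }

  # --- fit ------------------------------------------------------------
  if (stage_on("fit")) {
    t0 <- proc.time()[3]
    res$fit <- fit_yield_model(
      res$features, n_repeats = config$model$n_repeats,
      seed = substream_seed(config$seed, "model"),
      n_trees = config$model$n_trees, depth = config$model$depth,
      eta = config$model$eta, patience = config$model$patience,
      tune_iter = config$model$tune_iter)
    r2 <- res$fit$r2_global
    write_artifact(
      data.frame(repeat_id = seq_along(r2), signed_r2 = r2),
      pth("explained_variance.csv"), hash)
    write_artifact(stats::na.omit(predict_out_of_sample(res$fit)),
                   pth("predictions.csv"), hash)
    log_stage(log_path, "fit", nrow(res$features),
              length(r2), proc.time()[3] - t0)
  }

  # --- impacts --------------------------------------------------------
  if (stage_on("impacts") && !is.null(res$fit)) {
    t0 <- proc.time()[3]
    rows <- lapply(config$impacts$kinds, function(k) {
      est <- compound_scenario(res$fit, kind = k,
                               level = config$impacts$level_sigma,
                               sample_size = config$impacts$sample_size,
                               seed = substream_seed(config$seed, "impacts"))
      data.frame(kind = k, level_sigma = est$level, mean_pct = est$mean,
                 ci_lower = est$ci[1], ci_upper = est$ci[2],
                 mapped_pct = apply_zero_rule(est$mean, est$ci),
                 n_repeats = length(est$values))
    })
    res$scenarios <- do.call(rbind, rows)
    write_artifact(res$scenarios, pth("scenarios.csv"), hash)
    log_stage(log_path, "impacts", nrow(res$features),
              nrow(res$scenarios), proc.time()[3] - t0)
  }

  # --- trends ---------------------------------------------------------
  if (stage_on("trends")) {
    t0 <- proc.time()[3]
    trows <- list()
    for (pair in config$trends$pairs) {
      ev <- code_events(res$features, config$trends$threshold_sigma, pair)
      tf <- tryCatch(
        fit_logistic_trend(ev, n_boot = config$trends$n_boot,
                           seed = substream_seed(config$seed, "trends")),
        error = function(e) NULL)
      if (is.null(tf)) next
      trows[[pair]] <- data.frame(
        unit = "global", pair = pair, slope = tf$slope,
        odds_ratio = tf$odds_ratio, p_lrt = tf$p_lrt, p_t = tf$p_t,
        p_boot = tf$p_boot, significant = tf$significant,
        reported_or = tf$reported_or)
      if (pair == config$trends$pairs[1])
        write_artifact(probability_curve(tf, ev),
                       pth("probability_curve.csv"), hash)
    }
    res$trends <- do.call(rbind, trows)
    rownames(res$trends) <- NULL
    write_artifact(res$trends, pth("trends.csv"), hash)
    log_stage(log_path, "trends", nrow(res$features),
              nrow(res$trends %||% data.frame()), proc.time()[3] - t0)
  }

  invisible(res)
}
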