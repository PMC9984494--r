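test_that("config validation rejects impossible worlds", {
  expect_error(synth_config(n_years = 5), "10 years")
  expect_error(synth_config(temp_sm_corr = 0.3), "-1, 0")
  expect_error(synth_config(hotdry_penalty = 1.2), "0, 1")
  expect_error(synth_config(season_length_days = 400), "shorter")
  expect_error(synth_config(base_temp_by_cell = c(1, 2), n_cells = 3),
               "one entry per cell")
})

test_that("identical seeds give bit-identical worlds", {
  cfg <- synth_config(n_cells = 5, n_years = 10, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$weather, b$weather)
  expect_identical(a$yields, b$yields)
  expect_identical(a$calendar, b$calendar)
  expect_identical(a$truth$flags, b$truth$flags)
})

test_that("degenerate noise collapses temperature onto the cell baseline", {
  cfg <- synth_config(n_cells = 3, n_years = 10, temp_sd = 0,
                      seasonal_amplitude = 0, hotdry_base_prob = 0,
                      base_temp_by_cell = c(10, 20, 30), seed = 1)
  w <- generate_weather(cfg)
  for (i in 1:3)
    expect_equal(unique(w$tmean[i, ]), cfg$base_temp_by_cell[i])
  expect_true(all(w$tmin <= w$tmean & w$tmean <= w$tmax))
  expect_true(all(w$sm >= 0 & w$sm <= 1))
})

test_that("daily anomalies of temperature and soil moisture carry the configured correlation", {
  cfg <- synth_config(n_cells = 10, n_years = 30, temp_sm_corr = -0.6,
                      hotdry_base_prob = 0, seed = 4)
  w <- generate_weather(cfg)
  doy <- rep(seq_len(cfg$days_per_year), times = cfg$n_years)
  seasonal <- outer(cfg$base_temp_by_cell, rep(1, length(doy))) +
    cfg$seasonal_amplitude *
      matrix(sin(2 * pi * (doy - 120) / 365), 10, length(doy), byrow = TRUE)
  t_anom <- as.vector(w$tmean - seasonal)
  s_anom <- as.vector(w$sm - cfg$sm_mean)
  expect_gt(length(t_anom), 1e5)
  expect_lt(abs(cor(t_anom, s_anom) - (-0.6)), 0.05)
})

test_that("yields follow the constructed penalty and management trend", {
  # no penalty, no noise: pure management trend
  cfg0 <- synth_config(n_cells = 4, n_years = 12, hotdry_penalty = 0,
                       yield_noise_sd = 0, management_trend = 0.01, seed = 3)
  y0 <- generate_yields(generate_truth_flags(cfg0), cfg0)
  expect_equal(y0$yield, cfg0$yield_base * 1.01^(y0$year - 1),
               tolerance = 1e-12)

  # penalty 10%, no noise: flagged cell-years exactly 10% below trend
  cfg1 <- synth_config(n_cells = 10, n_years = 20, hotdry_penalty = 0.10,
                       yield_noise_sd = 0, hotdry_base_prob = 0.3, seed = 3)
  tr <- generate_truth_flags(cfg1)
  y1 <- generate_yields(tr, cfg1)
  flag <- tr$flags[cbind(y1$cell, y1$year)]
  trendline <- cfg1$yield_base * 1.01^(y1$year - 1)
  expect_equal(y1$yield[flag], 0.9 * trendline[flag], tolerance = 1e-12)
  expect_equal(y1$yield[!flag], trendline[!flag], tolerance = 1e-12)
})

test_that("with noise the flagged/unflagged yield ratio recovers the penalty", {
  cfg <- synth_config(n_cells = 100, n_years = 20, hotdry_penalty = 0.10,
                      yield_noise_sd = 0.03, hotdry_base_prob = 0.3,
                      hotdry_year_sd = 0, seed = 8)
  tr <- generate_truth_flags(cfg)
  y <- generate_yields(tr, cfg)
  flag <- tr$flags[cbind(y$cell, y$year)]
  expect_gt(sum(flag), 500)
  detrended <- y$yield / (cfg$yield_base * 1.01^(y$year - 1))
  ratio <- mean(detrended[flag]) / mean(detrended[!flag])
  expect_lt(abs(ratio - 0.90), 0.01)
})

test_that("calendar has regime lag, unit area weights and a wrap-around cell", {
  cfg <- synth_config(n_cells = 15, n_years = 10, seed = 2)
  cal <- generate_calendar(cfg)
  by_cell <- split(cal, cal$cell)
  for (d in by_cell) expect_equal(sum(d$area_frac), 1, tolerance = 1e-12)
  irr <- cal[cal$regime == "irrigated", ]
  rf <- cal[cal$regime == "rainfed", ]
  expect_equal(irr$harvest_doy, ((rf$harvest_doy - 15 - 1) %% 365) + 1)
  # at least one cell's 90-day window crosses the year boundary
  expect_true(any(rf$harvest_doy < 90))

  cfg0 <- synth_config(n_cells = 15, n_years = 10, calendar_lag_days = 0,
                       seed = 2)
  cal0 <- generate_calendar(cfg0)
  expect_identical(cal0$harvest_doy[cal0$regime == "irrigated"],
                   cal0$harvest_doy[cal0$regime == "rainfed"])
})

test_that("fitting the generative logistic model to truth flags recovers the injected slope", {
  slope <- 0.08
  reps <- 20
  est <- vapply(seq_len(reps), function(r) {
    cfg <- synth_config(n_cells = 200, n_years = 30, hotdry_base_prob = 0.02,
                        hotdry_trend_logodds_per_year = slope,
                        hotdry_year_sd = 0, seed = 1000 + r)
    tr <- generate_truth_flags(cfg)
    ev <- events_from_flags(tr$flags)
    yc <- ev$year - mean(unique(ev$year))
    unname(coef(glm(ev$event ~ yc, family = binomial()))[2])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - slope), 2 * mc_se + 1e-8)
})

test_that("a positive log-odds trend raises the compound-event probability over years", {
  cfg <- synth_config(n_cells = 300, n_years = 30, hotdry_base_prob = 0.02,
                      hotdry_trend_logodds_per_year = 0.08,
                      hotdry_year_sd = 0, seed = 5)
  tr <- generate_truth_flags(cfg)
  expect_true(all(diff(tr$prob_by_year) > 0))
  f_early <- mean(tr$flags[, 1:10])
  f_late <- mean(tr$flags[, 21:30])
  expect_gt(f_late, f_early)
})
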