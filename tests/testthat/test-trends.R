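test_that("event coding is an inclusive 1.5-sigma conjunction", {
  df <- data.frame(cell = 1:3, year = 1:3,
                   hot_days = c(1.6, 1.6, 0), dry_days = c(1.5, 1.4, 0),
                   cold_days = 0, wet_days = 0)
  fm <- make_feature_matrix(df, c("hot_days", "dry_days", "cold_days",
                                  "wet_days"))
  ev <- code_events(fm, 1.5, "hot-dry")
  expect_identical(ev$event, c(TRUE, FALSE, FALSE))
  # single-variable panels for the sensitivity trends
  expect_identical(code_events(fm, 1.5, "hot")$event, c(TRUE, TRUE, FALSE))
  expect_identical(code_events(fm, 1.5, "cold-wet")$event,
                   c(FALSE, FALSE, FALSE))
  # raising the threshold never increases the event count
  for (thr in c(0.5, 1.0, 1.5, 2.0)) {
    n1 <- sum(code_events(fm, thr, "hot")$event)
    n2 <- sum(code_events(fm, thr + 0.5, "hot")$event)
    expect_lte(n2, n1)
  }
})

test_that("logistic trend fits agree with an independent Newton solver", {
  set.seed(61)
  for (i in 1:5) {
    n <- 400
    yr <- sample(1:25, n, replace = TRUE)
    yc <- yr - mean(unique(yr))
    p <- plogis(-2.5 + 0.07 * yc)
    ev <- data.frame(cell = seq_len(n), year = yr,
                     event = runif(n) < p)
    class(ev) <- c("event_series", "data.frame")
    if (sum(ev$event) %in% c(0, n)) next
    fit <- fit_logistic_trend(ev, n_boot = 10, seed = 1)
    oracle <- newton_logistic(ev$year - mean(unique(ev$year)), ev$event)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-6)
    expect_equal(fit$slope, oracle[2], tolerance = 1e-6)
  }
})

test_that("a constant 50% event probability yields no trend and unit odds ratio", {
  set.seed(62)
  flags <- matrix(runif(200 * 30) < 0.5, 200, 30)
  fit <- fit_logistic_trend(events_from_flags(flags), n_boot = 50, seed = 2)
  expect_lt(abs(fit$slope), 0.01)
  expect_lt(abs(fit$odds_ratio - 1), 0.01)
})

test_that("odds-ratio reporting is gated on the triple significance test", {
  set.seed(63)
  flags <- matrix(runif(100 * 30) <
                    rep(plogis(-3 + 0.1 * (0:29)), each = 100), 100, 30)
  fit <- fit_logistic_trend(events_from_flags(flags), n_boot = 100, seed = 3)
  expect_true(fit$significant)
  expect_equal(fit$reported_or, fit$odds_ratio)
  # force one gate to fail: reported OR must drop to one
  fit2 <- fit
  fit2$p_boot <- 0.2
  fit2$significant <- all(c(fit2$p_lrt, fit2$p_t, fit2$p_boot) < 0.05)
  fit2$reported_or <- if (fit2$significant) fit2$odds_ratio else 1
  expect_false(fit2$significant)
  expect_equal(fit2$reported_or, 1)
})

test_that("complete separation is flagged and reported as no trend", {
  flags <- matrix(FALSE, 50, 30)
  flags[, 26:30] <- TRUE
  fit <- fit_logistic_trend(events_from_flags(flags), n_boot = 10, seed = 4)
  expect_true(fit$separation)
  expect_false(fit$significant)
  expect_equal(fit$reported_or, 1)
})

test_that("trend fit input contracts are enforced", {
  expect_error(fit_logistic_trend(events_from_flags(matrix(TRUE, 5, 1))),
               "2 distinct years")
  expect_error(fit_logistic_trend(events_from_flags(matrix(TRUE, 5, 10))),
               "non-event")
})

test_that("probability curves invert the logit and track empirical fractions", {
  fit <- structure(list(intercept = qlogis(0.02), slope = 0,
                        year_center = 15.5), class = "trend_fit")
  ev <- events_from_flags(matrix(FALSE, 10, 30))
  ev$event[ev$year == 3] <- TRUE # 100% in year 3
  pc <- probability_curve(fit, ev)
  expect_equal(pc$fitted_prob, rep(0.02, 30), tolerance = 1e-12)
  expect_equal(pc$empirical_frac[3], 1)
  expect_equal(pc$empirical_frac[4], 0)
  fit$slope <- 0.1
  expect_true(all(diff(probability_curve(fit, ev)$fitted_prob) > 0))
})

test_that("bootstrap bands are deterministic and degenerate at one resample", {
  set.seed(64)
  flags <- matrix(runif(50 * 20) < 0.1, 50, 20)
  ev <- events_from_flags(flags)
  b1 <- bootstrap_uncertainty_band(ev, n_boot = 1, seed = 5)
  expect_equal(b1$lower, b1$upper)
  expect_equal(b1$lower, b1$curves[, 1])
  b2 <- bootstrap_uncertainty_band(ev, n_boot = 20, seed = 6)
  b3 <- bootstrap_uncertainty_band(ev, n_boot = 20, seed = 6)
  expect_identical(b2, b3)
})

test_that("temporal-quintile log-odds are collinear under a linear trend", {
  set.seed(65)
  flags <- matrix(runif(2000 * 30) <
                    rep(plogis(-3 + 0.08 * (0:29)), each = 2000), 2000, 30)
  lc <- logodds_linearity_check(events_from_flags(flags))
  expect_equal(nrow(lc), 5L)
  r2 <- summary(lm(logodds ~ mid_year, lc))$r.squared
  expect_gt(r2, 0.9)

  # constant probability: flat profile
  set.seed(66)
  flags2 <- matrix(runif(2000 * 30) < 0.1, 2000, 30)
  lc2 <- logodds_linearity_check(events_from_flags(flags2))
  expect_lt(diff(range(lc2$logodds)), 0.3)

  # a zero-event block stays finite through the continuity correction
  flags3 <- matrix(FALSE, 10, 30)
  flags3[, 25:30] <- runif(60) < 0.5
  lc3 <- logodds_linearity_check(events_from_flags(flags3))
  expect_true(all(is.finite(lc3$logodds)))
})
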