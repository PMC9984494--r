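test_that("sine interpolation matches the closed form and stays within bounds", {
  # 4 samples over one period: phases 0, pi/2, pi, 3pi/2
  s <- interpolate_daily_temperature(0, 10, 4L)
  expect_equal(sort(as.vector(s)), c(0, 5, 5, 10), tolerance = 1e-12)

  s20 <- interpolate_daily_temperature(20, 20, 24L)
  expect_true(all(s20 == 20))

  s24 <- interpolate_daily_temperature(10, 30, 24L)
  expect_equal(mean(s24), 20, tolerance = 1e-9)
  expect_true(all(s24 >= 10 & s24 <= 30))

  expect_error(interpolate_daily_temperature(5, 2, 4L), "tmin exceeds tmax")
})

test_that("soil-moisture deficit is the rescaled complement of soil moisture", {
  expect_equal(soil_moisture_to_deficit(0.4, 0.1, 0.4), 0)
  expect_equal(soil_moisture_to_deficit(0.1, 0.1, 0.4), 1)
  expect_equal(soil_moisture_to_deficit(0.25, 0.1, 0.4), 0.5)
  expect_error(soil_moisture_to_deficit(0.2, 0.3, 0.3), "degenerate")
})

test_that("season windows end at harvest and wrap the year boundary", {
  expect_equal(extract_season_window(200, 1, 90), 111:200)
  # harvest doy 30, year 2: previous-year days 306..365 plus days 1..30
  expect_equal(extract_season_window(30, 2, 90), 306:395)
  expect_equal(extract_season_window(200, 1, 1), 200L)
  expect_error(extract_season_window(30, 1, 90), "before the first")
  expect_null(extract_season_window(30, 1, 90, strict = FALSE))
})

test_that("seasonal histograms conserve day mass and clamp outliers", {
  cube <- structure(list(
    tmin = matrix(20, 1, 90), tmax = matrix(20, 1, 90),
    tmean = matrix(20, 1, 90), precip = matrix(2, 1, 90),
    sm = matrix(seq(0.1, 0.5, length.out = 90), 1, 90),
    n_cells = 1L, n_years = 1L, days_per_year = 90L),
    class = "weather_cube")
  h <- accumulate_histograms(cube, 1, 1:90, 24L)
  expect_equal(sum(h$temp_counts), 90)
  expect_equal(sum(h$deficit_counts), 90)
  # constant 20 degC occupies the single bin [20, 20.1)
  expect_equal(h$temp_counts[temp_bin_index(20)], 90)
  expect_equal(sum(h$temp_counts > 0), 1L)

  # constant deficit 0.5005 lands in the bin covering [0.500, 0.501)
  cube2 <- cube
  cube2$sm <- matrix(1 - 0.5005, 1, 90)
  h2 <- accumulate_histograms(cube2, 1, 1:90, 24L,
                              deficit_ref = list(min = 0, max = 1))
  expect_equal(h2$deficit_counts[501], 90)

  # pathological 75 degC clamps into the top temperature bin
  cube3 <- cube
  cube3$tmin <- matrix(75, 1, 90)
  cube3$tmax <- matrix(75, 1, 90)
  h3 <- accumulate_histograms(cube3, 1, 1:90, 24L)
  expect_equal(h3$temp_counts[800], 90)
  expect_equal(sum(h3$temp_counts), 90)
})

test_that("regime merging is an exact area-weighted bin-wise average", {
  mk <- function(bins) {
    tc <- numeric(800); tc[bins] <- 90 / length(bins)
    dc <- numeric(1000); dc[bins] <- 90 / length(bins)
    structure(list(temp_counts = tc, deficit_counts = dc,
                   season_length = 90, cell = 1L, samples_per_day = 24L),
              class = "season_histogram")
  }
  a <- mk(100:109)
  b <- mk(200:219)
  expect_identical(merge_regimes(a, b, 1, 0)$temp_counts, a$temp_counts)
  expect_identical(merge_regimes(a, a, 0.5, 0.5)$temp_counts, a$temp_counts)
  m <- merge_regimes(a, b, 0.3, 0.7)
  expect_equal(m$temp_counts, 0.3 * a$temp_counts + 0.7 * b$temp_counts)
  expect_equal(sum(m$temp_counts), 90)
  expect_error(merge_regimes(a, b, 0.3, 0.6), "sum to 1")
})

test_that("percentile thresholds agree with brute force and are order invariant", {
  mk_bin <- function(bin) {
    tc <- numeric(800); tc[bin] <- 1
    structure(list(temp_counts = tc, deficit_counts = numeric(1000),
                   season_length = 1, cell = 1L, samples_per_day = 1L),
              class = "season_histogram")
  }
  # uniform pool over bins 1..100: the 90th (10th) percentile point sits at
  # the upper edge of bin 90 (bin 10), matching the brute-force percentile
  pool <- lapply(1:100, mk_bin)
  t90 <- percentile_threshold(pool, 90, "temp")
  t10 <- percentile_threshold(pool, 10, "temp")
  expect_equal(t90$bin, 90L)
  expect_equal(t90$frac, 1)
  expect_equal(t10$bin, 10L)
  expect_gte(t90$bin, t10$bin)
  # counts implied by the uniform pool: exactly 10% beyond each threshold
  expect_equal(sum(vapply(pool, function(h)
    count_extreme_days(h, t90, "above", "temp"), numeric(1))), 10)
  expect_equal(sum(vapply(pool, function(h)
    count_extreme_days(h, t10, "below", "temp"), numeric(1))), 10)
  # invariant to the order years are pooled in
  expect_equal(percentile_threshold(rev(pool), 90, "temp"), t90)
  # all mass in one bin: the threshold is that bin for any q
  one <- list(mk_bin(37))
  for (q in c(5, 50, 95))
    expect_equal(percentile_threshold(one, q, "temp")$bin, 37L)
  zero <- mk_bin(1)
  zero$temp_counts[] <- 0
  expect_error(percentile_threshold(list(zero), 50, "temp"), "empty pool")
})

test_that("extreme-day counts exclude the threshold bin and empty tails give zero", {
  tc <- numeric(800); tc[300:309] <- 9
  h <- structure(list(temp_counts = tc, deficit_counts = numeric(1000),
                      season_length = 90, cell = 1L, samples_per_day = 24L),
                 class = "season_histogram")
  expect_equal(count_extreme_days(h, 309L, "above", "temp"), 0)
  expect_equal(count_extreme_days(h, 300L, "below", "temp"), 0)
  expect_equal(count_extreme_days(h, 305L, "above", "temp"), 4 * 9)
  expect_equal(count_extreme_days(h, 305L, "below", "temp"), 5 * 9)
})

test_that("season means and totals follow direct arithmetic", {
  nd <- 500L
  cube <- structure(list(
    tmin = matrix(15, 1, nd), tmax = matrix(25, 1, nd),
    tmean = matrix(20, 1, nd), precip = matrix(2, 1, nd),
    sm = matrix(0.3, 1, nd), n_cells = 1L, n_years = 1L,
    days_per_year = nd), class = "weather_cube")
  s <- season_means_and_totals(cube, 1, 411:500)
  expect_equal(s$mean_temp, 20)
  expect_equal(s$mean_sm, 0.3)
  expect_equal(s$gs_precip, 180)
  expect_equal(s$annual_precip, 730)
  expect_lte(s$gs_precip, s$annual_precip)
  expect_error(season_means_and_totals(cube, 1, 111:200), "too short")
})

test_that("histogram-based counts match brute-force counts on raw series", {
  w <- world_small()
  for (cell in c(1, 7, 13)) {
    bf <- brute_force_counts(w$ds$weather, w$ds$calendar, cell)
    got <- w$ind[w$ind$cell == cell, ]
    expect_equal(got$year, bf$year)
    for (v in c("hot", "dry", "cold", "wet")) {
      expect_lt(max(abs(got[[paste0(v, "_days")]] - bf[[v]])), 1.5,
                label = paste("cell", cell, v, "count deviation"))
    }
  }
})

test_that("per-cell mean extreme counts sit at the percentile-implied fraction", {
  w <- world_small()
  for (v in c("hot_days", "dry_days", "cold_days", "wet_days")) {
    per_cell <- tapply(w$ind[[v]], w$ind$cell, mean)
    expect_true(all(abs(per_cell - 9) < 1.5),
                label = paste(v, "mean within binning tolerance of 10%"))
  }
})
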