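# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the code paths they validate.

# Newton-Raphson maximum-likelihood logistic regression (intercept + one
# covariate); the independent solver against which glm-based trend fits are
# checked.
newton_logistic <- function(x, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-(X %*% beta)))
    w <- as.vector(p * (1 - p))
    step <- solve(t(X) %*% (X * w), t(X) %*% (y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Brute-force extreme-day counts straight from the raw (un-binned) daily and
# sub-daily series: weighted percentile by sorting the pooled raw values,
# then counting raw samples beyond it. No histograms anywhere.
brute_force_counts <- function(weather, calendar, cell, window_days = 90,
                               samples_per_day = 24, q_upper = 90,
                               q_lower = 10) {
  dpy <- weather$days_per_year
  regimes <- split(calendar, calendar$regime)
  harv <- vapply(regimes, function(d) d$harvest_doy[d$cell == cell],
                 numeric(1))
  frac <- vapply(regimes, function(d) d$area_frac[d$cell == cell],
                 numeric(1))
  sm_min <- min(weather$sm[cell, ])
  sm_max <- max(weather$sm[cell, ])

  usable <- Filter(function(yr) {
    all(vapply(harv, function(h) {
      end <- (yr - 1) * dpy + h
      end - window_days + 1 >= 1 && end - 364 >= 1
    }, logical(1)))
  }, seq_len(weather$n_years))

  season <- function(h, yr) {
    end <- (yr - 1) * dpy + h
    idx <- (end - window_days + 1):end
    tm <- weather$tmin[cell, idx]
    tx <- weather$tmax[cell, idx]
    phases <- 2 * pi * (seq_len(samples_per_day) - 1) / samples_per_day
    temps <- as.vector((tm + tx) / 2 + outer((tx - tm) / 2, sin(phases)))
    defs <- (sm_max - weather$sm[cell, idx]) / (sm_max - sm_min)
    list(temps = temps, defs = defs)
  }
  seasons <- lapply(usable, function(yr) {
    lapply(seq_along(harv), function(i) season(harv[i], yr))
  })

  wq <- function(vals, wts, q) { # weighted percentile by sorting
    o <- order(vals)
    cw <- cumsum(wts[o]) / sum(wts)
    vals[o][which(cw >= q / 100 - 1e-12)[1]]
  }
  pool <- function(field) {
    vals <- unlist(lapply(seasons, function(s)
      unlist(lapply(s, `[[`, field))))
    per_sample <- unlist(lapply(seasons, function(s)
      unlist(lapply(seq_along(s), function(i)
        rep(frac[i], length(s[[i]][[field]]))))))
    list(vals = vals, wts = per_sample)
  }
  tp <- pool("temps")
  dp <- pool("defs")
  thr <- list(hot = wq(tp$vals, tp$wts, q_upper),
              cold = wq(tp$vals, tp$wts, q_lower),
              dry = wq(dp$vals, dp$wts, q_upper),
              wet = wq(dp$vals, dp$wts, q_lower))

  counts <- t(vapply(seasons, function(s) {
    cnt <- function(field, th, above, div) {
      sum(vapply(seq_along(s), function(i) {
        v <- s[[i]][[field]]
        frac[i] * if (above) sum(v > th) else sum(v < th)
      }, numeric(1))) / div
    }
    c(hot = cnt("temps", thr$hot, TRUE, samples_per_day),
      dry = cnt("defs", thr$dry, TRUE, 1),
      cold = cnt("temps", thr$cold, FALSE, samples_per_day),
      wet = cnt("defs", thr$wet, FALSE, 1))
  }, numeric(4)))
  data.frame(cell = cell, year = usable, hot = counts[, "hot"],
             dry = counts[, "dry"], cold = counts[, "cold"],
             wet = counts[, "wet"])
}

# bare event_series builder for trend tests that start from flag panels
events_from_flags <- function(flags) {
  out <- data.frame(cell = as.vector(row(flags)),
                    year = as.vector(col(flags)),
                    event = as.vector(flags))
  class(out) <- c("event_series", "data.frame")
  out
}

# minimal feature_matrix builder for unit tests
make_feature_matrix <- function(df, feature_cols) {
  if (is.null(df$area_total)) df$area_total <- 1
  attr(df, "feature_cols") <- feature_cols
  class(df) <- c("feature_matrix", "data.frame")
  df
}
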