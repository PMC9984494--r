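#' Randomly split years into blocked train/eval/test groups
#'
#' Years are shuffled and dealt into `n_groups` groups of near-equal size
#' (within one year). Each group takes the held-out prediction role in one
#' fold; of the remaining groups, one (rotating) is used to monitor early
#' stopping and the rest train the model. Blocking whole years keeps the
#' held-out predictions out of sample with respect to shared weather within
#' a year.
#'
#' @param years vector of distinct years.
#' @param n_groups number of groups (4 in the main protocol).
#' @param seed RNG seed for the shuffle.
#' @return a `split_plan`: `year_group` (named integer vector), `folds`
#'   (list with `test_years`, `eval_years`, `train_years` per fold).
#' @export
make_split_plan <- function(years, n_groups = 4L, seed = 1L) {
  years <- unique(years)
  if (length(years) < 2L * n_groups) stop("too few years to split")
  set.seed(seed)
  shuffled <- sample(years)
  grp <- rep(seq_len(n_groups), length.out = length(shuffled))
  year_group <- stats::setNames(grp[match(years, shuffled)], years)
  folds <- lapply(seq_len(n_groups), function(k) {
    ev <- (k %% n_groups) + 1L
    list(test_years = years[year_group == k],
         eval_years = years[year_group == ev],
         train_years = years[!(year_group %in% c(k, ev))])
  })
  structure(list(year_group = year_group, folds = folds, seed = seed),
            class = "split_plan")
}

#' Sample regularising hyperparameter candidates
#'
#' Draws uniformly from the search boxes: training-row subsample fraction
#' and per-tree feature fraction in `[0.5, 1]`, L2 penalty (lambda) in
#' `[0.5, 1.5]`, minimum split-gain penalty (gamma) in `[0, 0.05]`.
#'
#' @param n number of candidates.
#' @return data frame with columns subsample, colsample, lambda, gamma.
#' @export
sample_hyperparameters <- function(n) {
  data.frame(subsample = stats::runif(n, 0.5, 1),
             colsample = stats::runif(n, 0.5, 1),
             lambda = stats::runif(n, 0.5, 1.5),
             gamma = stats::runif(n, 0, 0.05))
}

xgb_params <- function(hp, depth, eta) {
  list(objective = "reg:squarederror", max_depth = depth, eta = eta,
       subsample = hp$subsample, colsample_bytree = hp$colsample,
       lambda = hp$lambda, gamma = hp$gamma, nthread = 1L,
       seed = sample.int(.Machine$integer.max, 1L))
}

#' Fit one boosted-tree fold with patience-based early stopping
#'
#' Trains a gradient-boosted tree regressor (squared-error objective) on the
#' training rows, monitoring RMSE on a year-disjoint evaluation set.
#' Boosting halts after `patience` rounds without improvement over the best
#' evaluation error, and the model at the best round is used for
#' prediction.
#'
#' @param x_train,y_train training features/response.
#' @param x_eval,y_eval early-stopping evaluation features/response.
#' @param hp one-row hyperparameter data frame from
#'   [sample_hyperparameters()].
#' @param n_trees maximum number of trees.
#' @param depth maximum tree depth.
#' @param eta learning rate.
#' @param patience early-stopping patience in rounds.
#' @return an `xgb.Booster`.
#' @export
fit_fold <- function(x_train, y_train, x_eval, y_eval, hp,
                     n_trees = 400L, depth = 3L, eta = 0.1,
                     patience = 40L) {
  if (!nrow(x_train) || !nrow(x_eval)) stop("empty training or evaluation set")
  dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train, nthread = 1L)
  deval <- xgboost::xgb.DMatrix(x_eval, label = y_eval, nthread = 1L)
  xgboost::xgb.train(params = xgb_params(hp, depth, eta), data = dtrain,
                     nrounds = n_trees, evals = list(eval = deval),
                     early_stopping_rounds = patience, verbose = 0)
}

best_eval_rmse <- function(model) {
  min(attributes(model)$evaluation_log$eval_rmse)
}

#' Randomised hyperparameter search with year-wise cross-validation
#'
#' Samples `n_iter` candidate quadruples from the search boxes and scores
#' each by mean RMSE under threefold cross-validation whose folds hold
#' disjoint sets of years. The first candidate attaining the lowest mean
#' error wins.
#'
#' @param x,y training features/response.
#' @param years year of each training row.
#' @param n_iter number of sampled candidates.
#' @param n_trees,depth,eta,patience boosting settings as in [fit_fold()].
#' @return the winning one-row hyperparameter data frame, with the mean CV
#'   RMSE in column `cv_rmse`.
#' @export
tune_hyperparameters <- function(x, y, years, n_iter = 5L,
                                 n_trees = 400L, depth = 3L, eta = 0.1,
                                 patience = 40L) {
  uy <- unique(years)
  if (length(uy) < 3L) stop("training data must span at least 3 years")
  cand <- sample_hyperparameters(n_iter)
  fold_of <- stats::setNames(rep(1:3, length.out = length(uy)), sample(uy))
  row_fold <- fold_of[as.character(years)]
  cand$cv_rmse <- vapply(seq_len(n_iter), function(i) {
    mean(vapply(1:3, function(f) {
      tr <- row_fold != f
      m <- fit_fold(x[tr, , drop = FALSE], y[tr],
                    x[!tr, , drop = FALSE], y[!tr],
                    cand[i, ], n_trees, depth, eta, patience)
      best_eval_rmse(m)
    }, numeric(1)))
  }, numeric(1))
  cand[which.min(cand$cv_rmse), , drop = FALSE]
}

#' Fit the repeated year-blocked out-of-sample yield model
#'
#' The full protocol: for each repeat, years are randomly split into four
#' groups; each group in turn is held out while the other three supply two
#' training groups and one early-stopping evaluation group. Before each
#' fold's final fit, a randomised hyperparameter search (default 5
#' candidates, threefold year-wise CV on the three non-held-out groups)
#' picks the regularisation settings. Held-out predictions across the four
#' folds form a continuous out-of-sample series per cell; the per-repeat
#' explained variance is the sign-preserved squared Pearson correlation of
#' the area-weighted yearly aggregated reported and predicted anomalies.
#'
#' @param features a `feature_matrix` from [standardize_features()].
#' @param n_repeats number of re-randomised repeats (100 in the full
#'   protocol; 10 is a practical desk default).
#' @param seed master seed; each repeat uses a derived substream.
#' @param n_trees,depth,eta,patience boosting settings.
#' @param tune_iter candidates per randomised search (0 disables tuning and
#'   uses mid-box defaults).
#' @return a `cropext_fit`: per-repeat fold models, split plans, chosen
#'   hyperparameters, out-of-sample prediction matrix (rows as in
#'   `features`, one column per repeat), and `r2_global` per repeat.
#' @export
fit_yield_model <- function(features, n_repeats = 10L, seed = 1L,
                            n_trees = 400L, depth = 3L, eta = 0.1,
                            patience = 40L, tune_iter = 5L) {
  stopifnot(inherits(features, "feature_matrix"))
  fcols <- attr(features, "feature_cols")
  x <- as.matrix(features[, fcols])
  y <- features$yield_anom
  yrs <- features$year
  pred <- matrix(NA_real_, nrow(x), n_repeats)
  models <- vector("list", n_repeats)
  plans <- vector("list", n_repeats)
  hplog <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- substream_seed(seed, paste0("repeat", r))
    plan <- make_split_plan(unique(yrs), 4L, rs)
    set.seed(substream_seed(rs, "fit"))
    fold_models <- vector("list", 4L)
    fold_hp <- vector("list", 4L)
    for (k in 1:4) {
      fold <- plan$folds[[k]]
      tr <- yrs %in% fold$train_years
      ev <- yrs %in% fold$eval_years
      te <- yrs %in% fold$test_years
      hp <- if (tune_iter > 0L) {
        pool <- tr | ev
        tune_hyperparameters(x[pool, , drop = FALSE], y[pool], yrs[pool],
                             tune_iter, n_trees, depth, eta, patience)
      } else {
        data.frame(subsample = 0.75, colsample = 0.75, lambda = 1,
                   gamma = 0.025, cv_rmse = NA_real_)
      }
      m <- fit_fold(x[tr, , drop = FALSE], y[tr],
                    x[ev, , drop = FALSE], y[ev],
                    hp, n_trees, depth, eta, patience)
      pred[te, r] <- predict(m, x[te, , drop = FALSE])
      fold_models[[k]] <- m
      fold_hp[[k]] <- hp
    }
    models[[r]] <- fold_models
    plans[[r]] <- plan
    hplog[[r]] <- do.call(rbind, fold_hp)
  }
  r2 <- vapply(seq_len(n_repeats), function(r) {
    explained_variance(y, pred[, r], features$area_total, yrs)
  }, numeric(1))
  structure(list(features = features, feature_cols = fcols,
                 predictions = pred, models = models, plans = plans,
                 hyperparameters = hplog, r2_global = r2,
                 n_repeats = n_repeats, seed = seed),
            class = "cropext_fit")
}

#' Out-of-sample predictions in long format
#'
#' @param fit a `cropext_fit`.
#' @return data frame: cell, year, repeat_id, predicted, reported.
#' @export
predict_out_of_sample <- function(fit) {
  stopifnot(inherits(fit, "cropext_fit"))
  n <- nrow(fit$features)
  data.frame(cell = rep(fit$features$cell, fit$n_repeats),
             year = rep(fit$features$year, fit$n_repeats),
             repeat_id = rep(seq_len(fit$n_repeats), each = n),
             predicted = as.vector(fit$predictions),
             reported = rep(fit$features$yield_anom, fit$n_repeats))
}

#' Sign-preserved squared Pearson correlation of aggregated anomalies
#'
#' Aggregates reported and predicted anomalies to one value per year with a
#' weighted (harvested-area) mean across cells, computes the Pearson
#' correlation of the two yearly series, and returns `sign(r) * r^2`.
#'
#' @param reported,predicted anomaly vectors (cell-year rows).
#' @param weights aggregation weights (harvested area per row).
#' @param years year of each row.
#' @return signed r-squared.
#' @export
explained_variance <- function(reported, predicted, weights, years) {
  ok <- is.finite(reported) & is.finite(predicted)
  agg <- function(v) {
    vapply(split(seq_along(years)[ok], years[ok]), function(i) {
      stats::weighted.mean(v[i], weights[i])
    }, numeric(1))
  }
  a <- agg(reported)
  b <- agg(predicted)
  if (length(a) < 3L) stop("fewer than 3 aggregated points")
  r <- stats::cor(a, b)
  sign(r) * r^2
}

#' Shapley feature attribution across all repeats and folds
#'
#' Computes additive per-observation feature contributions (tree SHAP) for
#' every fold model of every repeat and summarises them as the mean
#' absolute contribution per feature, averaged across models. Per
#' observation, contributions plus the base value reconstruct the model
#' prediction.
#'
#' @param fit a `cropext_fit`.
#' @param newdata optional feature matrix (defaults to the training
#'   features).
#' @return named numeric vector of mean absolute contributions per feature
#'   (yield-anomaly units); per-model matrix in attribute `per_model`.
#' @export
attribute_features <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "cropext_fit"))
  x <- if (is.null(newdata)) as.matrix(fit$features[, fit$feature_cols])
       else as.matrix(newdata[, fit$feature_cols])
  per_model <- t(vapply(unlist(fit$models, recursive = FALSE), function(m) {
    contrib <- predict(m, x, predcontrib = TRUE)
    colMeans(abs(contrib[, fit$feature_cols, drop = FALSE]))
  }, numeric(length(fit$feature_cols))))
  out <- colMeans(per_model)
  attr(out, "per_model") <- per_model
  out
}
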