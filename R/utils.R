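#' @importFrom stats predict
NULL

#' Derive a reproducible substream seed from a master seed
#'
#' Each randomised stage of the pipeline (weather anomalies, yield noise,
#' event flags, year splits, bootstrap resampling, ...) draws from its own
#' substream so that stages can be regenerated independently without
#' disturbing one another. The substream seed is a deterministic function of
#' the master seed and a stream label.
#'
#' @param seed master seed (integer).
#' @param stream character label of the stream, e.g. `"weather"`.
#' @return an integer seed below 2^31, suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483629 # large prime < 2^31
  h <- 17
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% m
  as.integer((abs(seed) + h * 7919) %% m)
}

# population standard deviation (divisor n, not n - 1); the sigma used for
# z-scoring and hence for the 1.5-sigma event coding
sd_pop <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

#' Z-score a vector using the population standard deviation
#'
#' Constant vectors (population sd below `tol`) map to all zeros rather than
#' NaN; this is the degenerate-column rule used throughout feature
#' standardisation.
#'
#' @param x numeric vector.
#' @param tol sd below which the column is treated as constant.
#' @return numeric vector of z-scores.
#' @export
zscore <- function(x, tol = 1e-12) {
  s <- sd_pop(x)
  if (!is.finite(s) || s < tol) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# FNV-1a style hash of a config (via its canonical JSON form), kept below
# 2^31 so it prints as a plain integer. Used to stamp artifact tables.
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  m <- 2147483629
  h <- 2166136261 %% m
  for (b in utf8ToInt(as.character(txt))) h <- ((h + b) * 16777) %% m
  sprintf("%d", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
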