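# Artifact tables are plain CSV with a one-line "# key: value" header
# carrying the config hash, so a run directory is self-describing and
# mixing artifacts from different configurations is detectable.

#' Write an artifact table stamped with the configuration hash
#'
#' @param df data frame to write.
#' @param path output path (CSV).
#' @param hash configuration hash string from the run.
#' @export
write_artifact <- function(df, path, hash) {
  # doubles are written with 17 significant digits so artifacts round-trip
  # bit-exactly through read.csv
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an artifact table, optionally checking its configuration hash
#'
#' @param path artifact path.
#' @param expect_hash if given, error when the stored hash differs.
#' @return data frame with attribute `config_hash`.
#' @export
read_artifact <- function(path, expect_hash = NULL) {
  header <- readLines(path, n = 1L)
  hash <- sub("^# config_hash: ", "", header)
  if (!is.null(expect_hash) && !identical(hash, expect_hash))
    stop("artifact ", basename(path), " was produced by a different config (",
         hash, " != ", expect_hash, ")")
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- hash
  df
}

#' Write a weather cube as a long gridded time-series table
#'
#' One row per (cell, day): year, day-of-year, tmin, tmax, tmean, precip,
#' sm. A plain-text stand-in for a NetCDF-style raster time series.
#'
#' @param weather a `weather_cube`.
#' @param path output path (CSV).
#' @param hash configuration hash string.
#' @export
write_weather_csv <- function(weather, path, hash = "") {
  nd <- ncol(weather$tmean)
  dpy <- weather$days_per_year
  df <- data.frame(
    cell = rep(seq_len(weather$n_cells), times = nd),
    year = rep(rep(seq_len(weather$n_years), each = dpy),
               each = weather$n_cells),
    doy = rep(rep(seq_len(dpy), times = weather$n_years),
              each = weather$n_cells),
    tmin = as.vector(weather$tmin), tmax = as.vector(weather$tmax),
    tmean = as.vector(weather$tmean), precip = as.vector(weather$precip),
    sm = as.vector(weather$sm))
  write_artifact(df, path, hash)
}

#' Read a weather cube from its long table representation
#'
#' @param path path written by [write_weather_csv()].
#' @return a `weather_cube`.
#' @export
read_weather_csv <- function(path) {
  df <- read_artifact(path)
  n_cells <- max(df$cell)
  dpy <- max(df$doy)
  n_years <- max(df$year)
  df <- df[order((df$year - 1L) * dpy + df$doy, df$cell), ]
  shape <- function(v) matrix(v, n_cells, n_years * dpy)
  structure(list(tmin = shape(df$tmin), tmax = shape(df$tmax),
                 tmean = shape(df$tmean), precip = shape(df$precip),
                 sm = shape(df$sm), n_cells = n_cells, n_years = n_years,
                 days_per_year = dpy),
            class = "weather_cube")
}
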