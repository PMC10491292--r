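#' Read and write the flat-file schemas used by the pipeline
#'
#' CSV readers/writers for the four input schemas and the two result
#' tables: daily station records (`station_id`, `date`, `t_max`, `t_min`,
#' `t_mean`, `rh_max`, `rh_min`, `rh_mean`), station metadata
#' (`station_id`, `latitude`, `longitude`, `elevation_m`, `is_land`,
#' `record_start`, `temp_inhomogeneity`), annual GMST anomalies (`year`,
#' `anomaly_c`) and calibration points (`temperature_c`, `humidity_pct`,
#' `label`). Readers validate the column set; writers are thin
#' `write.csv` wrappers.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return Readers return a validated data.frame (dates parsed as `Date`);
#'   writers return `path` invisibly.
#' @name station_io
NULL

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(miss, collapse = ", ")))
  }
  df
}

#' @rdname station_io
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("station_id", "date", daily_fields), "station CSV")
  df$date <- as.Date(df$date)
  df
}

#' @rdname station_io
#' @export
write_station_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname station_io
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("station_id", "latitude", "longitude", "is_land",
                      "temp_inhomogeneity"), "metadata CSV")
  df$is_land <- as.logical(df$is_land)
  if ("record_start" %in% names(df)) df$record_start <- as.Date(df$record_start)
  df
}

#' @rdname station_io
#' @export
read_gmst_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("year", "anomaly_c"), "GMST CSV")
  df
}

#' @rdname station_io
#' @examples
#' pts <- read_calibration_csv(system.file("extdata",
#'   "synthetic_calibration_points.csv", package = "noncompheat"))
#' fit_threshold(pts)
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("temperature_c", "humidity_pct"), "calibration CSV")
  df
}

#' Export an hourly series as CSV
#'
#' Writes `timestamp` (ISO 8601, UTC), `temperature_c`, `humidity_pct` and,
#' when present, `exceedance`.
#'
#' @param hourly data.frame from [reconstruct_hourly()], optionally with an
#'   `exceedance` column.
#' @param path file path.
#' @export
write_hourly_csv <- function(hourly, path) {
  out <- hourly
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$year <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
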