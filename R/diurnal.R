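#' Reconstruct hourly temperature and humidity from daily statistics
#'
#' Builds hourly series from daily max/min/mean by a fixed-frequency
#' sinusoid: only the amplitude is fitted, the frequency is 24 h and
#' temperature and relative humidity are in antiphase (180 degrees apart).
#' For each day,
#' `T(h) = t_mean + A_T * cos(2*pi*(h - t_peak_hour)/24)` with
#' `A_T = (t_max - t_min)/2`, and
#' `RH(h) = rh_mean + A_RH * cos(2*pi*(h - t_peak_hour - 12)/24)` with
#' `A_RH = (rh_max - rh_min)/2`, clipped to [0, 100].
#'
#' The reconstructed daily mean equals the input mean exactly (a cosine
#' sampled at 24 equispaced points sums to zero); the daily max/min are
#' honored only when the input mean equals (max+min)/2, since a pure
#' sinusoid cannot match all three otherwise.
#'
#' @param daily data.frame with columns `date` (Date), `t_max`, `t_min`,
#'   `t_mean` (degC), `rh_max`, `rh_min`, `rh_mean` (percent). Days with any
#'   missing field yield missing hourly values (gap filling happens
#'   upstream).
#' @param t_peak_hour clock hour of the temperature maximum (default 15:00
#'   local, climatologically typical); the humidity peak is 12 h later.
#' @return data.frame with `timestamp` (POSIXct, UTC), `temperature_c`,
#'   `humidity_pct`; 24 rows per input day.
#' @export
reconstruct_hourly <- function(daily, t_peak_hour = 15) {
  req <- c("date", "t_max", "t_min", "t_mean", "rh_max", "rh_min", "rh_mean")
  stopifnot(is.data.frame(daily), all(req %in% names(daily)))
  n <- nrow(daily)
  h <- 0:23
  amp_t <- (daily$t_max - daily$t_min) / 2
  amp_rh <- (daily$rh_max - daily$rh_min) / 2
  # outer products: n days x 24 hours, flattened day-major
  cos_t <- cos(2 * pi * (h - t_peak_hour) / 24)
  cos_rh <- cos(2 * pi * (h - t_peak_hour - 12) / 24)
  temp <- rep(daily$t_mean, each = 24) + rep(amp_t, each = 24) * rep(cos_t, n)
  rh <- rep(daily$rh_mean, each = 24) + rep(amp_rh, each = 24) * rep(cos_rh, n)
  rh <- pmin(pmax(rh, 0), 100)
  ts <- rep(as.POSIXct(daily$date, tz = "UTC"), each = 24) + rep(h, n) * 3600
  data.frame(timestamp = ts, temperature_c = temp, humidity_pct = rh)
}

# Rolling mean over windows of length k aligned at the window start:
# out[i] = mean(x[i .. i+k-1]); windows containing any NA are NA.
roll_mean_start <- function(x, k) {
  n <- length(x)
  if (n < k) return(numeric(0))
  xz <- ifelse(is.na(x), 0, x)
  cs <- cumsum(xz)
  cn <- cumsum(!is.na(x))
  wsum <- cs[k:n] - c(0, cs)[1:(n - k + 1)]
  wcnt <- cn[k:n] - c(0, cn)[1:(n - k + 1)]
  out <- wsum / k
  out[wcnt < k] <- NA_real_
  out
}

#' Maximum windowed-mean exceedance of a series
#'
#' The largest mean of the exceedance scalar over any contiguous window of
#' `window_hours` consecutive hours (windows roll freely across day
#' boundaries). With the default 6-hour window this is the annual block
#' maximum statistic when applied to one year of hourly exceedances.
#'
#' @param exceedance hourly exceedance scalar series.
#' @param window_hours window length in hours; 6 by default, 9 and 12 are
#'   the supported sensitivity settings.
#' @return list with `value` (max window mean; NA if every window contains a
#'   missing hour), `start_index` (1-based index of the first hour of the
#'   maximizing window, NA when value is NA) and `window_hours`.
#' @export
windowed_block_maximum <- function(exceedance, window_hours = 6) {
  stopifnot(length(exceedance) >= window_hours, window_hours >= 1)
  m <- roll_mean_start(exceedance, window_hours)
  if (all(is.na(m))) {
    return(list(value = NA_real_, start_index = NA_integer_,
                window_hours = window_hours))
  }
  i <- which.max(m)
  list(value = m[i], start_index = i, window_hours = window_hours)
}

#' Annual block maxima of the windowed exceedance scalar
#'
#' Computes, for each year, the maximum `window_hours`-mean exceedance over
#' all windows starting in that year (windows may cross calendar
#' boundaries; a window is attributed to the year of its first hour), and
#' pairs it with that year's global-mean surface temperature (GMST)
#' anomaly.
#'
#' @param hourly data.frame with `timestamp` (POSIXct) and `exceedance`;
#'   an optional integer `year` column short-circuits the (slow) timestamp
#'   formatting.
#' @param gmst data.frame with `year` and `anomaly_c` (GMST anomaly, degC
#'   above preindustrial); years without an entry get NA covariate.
#' @param window_hours window length in hours (default 6).
#' @return data.frame with `year`, `value`, `window_hours`, `covariate`.
#'   Years whose every window includes a missing hour have NA `value`.
#' @export
annual_block_maxima <- function(hourly, gmst = NULL, window_hours = 6) {
  stopifnot(all(c("timestamp", "exceedance") %in% names(hourly)))
  x <- hourly$exceedance
  m <- roll_mean_start(x, window_hours)
  yr <- if ("year" %in% names(hourly)) {
    as.integer(hourly$year)
  } else {
    as.integer(format(hourly$timestamp, "%Y"))
  }
  yr <- yr[seq_along(m)]
  vals <- tapply(m, yr, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  out <- data.frame(year = as.integer(names(vals)),
                    value = as.numeric(vals),
                    window_hours = window_hours)
  out$covariate <- if (is.null(gmst)) {
    NA_real_
  } else {
    gmst$anomaly_c[match(out$year, gmst$year)]
  }
  out[order(out$year), , drop = FALSE]
}

#' Count noncompensable heat events in an hourly series
#'
#' An event is `window_hours` consecutive noncompensable hours (exceedance
#' scalar strictly positive). Events are counted as maximal non-overlapping
#' windows tiled greedily left-to-right inside each run of consecutive
#' noncompensable hours, so a run of 13 hours contains two 6-hour events.
#'
#' @param exceedance hourly exceedance scalar (or already-binarized) series;
#'   missing hours break runs.
#' @param window_hours event duration in hours (default 6).
#' @return integer event count.
#' @export
count_noncompensable_events <- function(exceedance, window_hours = 6) {
  stopifnot(window_hours >= 1)
  hot <- !is.na(exceedance) & exceedance > 0
  r <- rle(hot)
  sum(r$lengths[r$values] %/% window_hours)
}
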