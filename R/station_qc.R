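#' Great-circle distance between stations
#'
#' Haversine distance in kilometres, via [geosphere::distHaversine()].
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

daily_fields <- c("t_max", "t_min", "t_mean", "rh_max", "rh_min", "rh_mean")

# Fraction of calendar days in [period[1], period[2]] for which the station
# has a row with all six daily fields present.
missing_fraction <- function(series, period) {
  d0 <- as.Date(sprintf("%d-01-01", period[1]))
  d1 <- as.Date(sprintf("%d-12-31", period[2]))
  expected <- as.integer(d1 - d0) + 1L
  in_per <- series$date >= d0 & series$date <= d1
  complete <- stats::complete.cases(series[in_per, daily_fields])
  1 - sum(complete) / expected
}

# Highest window-mean exceedance over the days of `series` with dates in
# [y0, y1]; NA when no complete day falls in the era.
era_peak_exceedance <- function(series, y0, y1, thr, window_hours) {
  yr <- as.integer(format(series$date, "%Y"))
  sub <- series[yr >= y0 & yr <= y1, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub[, daily_fields]), , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  hr <- reconstruct_hourly(sub)
  ex <- exceedance_scalar(hr$temperature_c, hr$humidity_pct, thr)
  windowed_block_maximum(ex, window_hours)$value
}

#' Staged station-selection filters
#'
#' Applies, in order: (1) remove non-land stations; (2) remove stations
#' poleward of 60 degrees latitude; (3) remove stations missing more than
#' half of their daily records in the analysis period; (4) remove stations
#' whose highest windowed-mean exceedance in an early era (1950-1990)
#' exceeds the highest in the recent era (after 2000) — guarding against
#' spurious early extremes; (5) remove stations whose temperature
#' inhomogeneity is missing or greater than 1 degC (inhomogeneity values
#' are consumed as metadata from an upstream pairwise homogenization).
#' Each removal is attributed to the first failing filter. The filters are
#' idempotent: refiltering a kept set removes nothing.
#'
#' @param meta station metadata data.frame: `station_id`, `latitude`,
#'   `longitude`, `is_land` (logical), `temp_inhomogeneity` (degC, NA when
#'   unavailable); other columns pass through.
#' @param daily long data.frame of daily records: `station_id`, `date`,
#'   `t_max`, `t_min`, `t_mean`, `rh_max`, `rh_min`, `rh_mean`.
#' @param thr `compensability_threshold` used for the early-maximum filter.
#' @param period analysis period, `c(first_year, last_year)`.
#' @param early_period era for the early-maximum comparison.
#' @param late_start first year of the recent era.
#' @param window_hours exposure window used by the early-maximum filter.
#' @param lat_limit absolute-latitude cutoff, degrees.
#' @param max_missing maximum tolerated missing fraction in the period.
#' @param max_inhomogeneity inhomogeneity cutoff, degC.
#' @return list with `kept` (metadata subset) and `report` (a `qc_report`:
#'   `counts` named integer vector of removals per filter plus `kept`, and
#'   `disposition` data.frame with one row per input station).
#' @export
filter_stations <- function(meta, daily, thr, period = c(1970, 2020),
                            early_period = c(1950, 1990), late_start = 2000,
                            window_hours = 6, lat_limit = 60,
                            max_missing = 0.5, max_inhomogeneity = 1) {
  filters <- c("nonland", "latitude", "missing", "early_maximum",
               "inhomogeneity")
  if (nrow(meta) == 0) {
    rep <- structure(list(
      counts = stats::setNames(c(integer(length(filters)), 0L),
                               c(filters, "kept")),
      disposition = data.frame(station_id = character(0),
                               status = character(0))), class = "qc_report")
    return(list(kept = meta, report = rep))
  }
  reason <- rep(NA_character_, nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    s <- daily[daily$station_id == m$station_id, , drop = FALSE]
    reason[i] <- if (!isTRUE(m$is_land)) {
      "nonland"
    } else if (abs(m$latitude) > lat_limit) {
      "latitude"
    } else if (missing_fraction(s, period) > max_missing) {
      "missing"
    } else {
      early <- era_peak_exceedance(s, early_period[1], early_period[2],
                                   thr, window_hours)
      late <- era_peak_exceedance(s, late_start, period[2] + 1000L,
                                  thr, window_hours)
      if (!is.na(early) && !is.na(late) && early > late) {
        "early_maximum"
      } else if (is.na(m$temp_inhomogeneity) ||
                 m$temp_inhomogeneity > max_inhomogeneity) {
        "inhomogeneity"
      } else {
        NA_character_
      }
    }
  }
  kept <- meta[is.na(reason), , drop = FALSE]
  counts <- vapply(filters, function(f) sum(reason == f, na.rm = TRUE),
                   integer(1))
  counts <- c(counts, kept = nrow(kept))
  disposition <- data.frame(
    station_id = meta$station_id,
    status = ifelse(is.na(reason), "kept", paste0("removed(", reason, ")")),
    stringsAsFactors = FALSE)
  list(kept = kept,
       report = structure(list(counts = counts, disposition = disposition),
                          class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Station QC report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-15s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

# Lengths of NA runs in a vector.
na_run_lengths <- function(x) {
  r <- rle(is.na(x))
  r$lengths[r$values]
}

#' Fill short missing runs by within-station harmonic regression
#'
#' For stations missing fewer than five consecutive observations, each
#' daily field is regressed on a linear trend plus annual and semiannual
#' harmonics fitted to the station's own non-missing days, and missing
#' values are replaced by the regression prediction. Humidity fields are
#' clipped to [0, 100]. Non-missing values are never altered.
#'
#' @param series one station's daily data.frame (`date` plus the six daily
#'   fields).
#' @param max_run longest admissible missing run (default 4); any longer
#'   run raises an error — such stations must go through
#'   [fill_long_gaps()].
#' @return the completed series.
#' @export
fill_short_gaps <- function(series, max_run = 4) {
  stopifnot(is.data.frame(series), "date" %in% names(series))
  for (f in daily_fields) {
    if (any(na_run_lengths(series[[f]]) > max_run)) {
      stop(sprintf(
        "field %s has a missing run longer than %d days; use fill_long_gaps",
        f, max_run))
    }
  }
  t_num <- as.numeric(series$date)
  doy <- as.numeric(format(series$date, "%j"))
  w <- 2 * pi * doy / 365.25
  X <- cbind(1, t_num, cos(w), sin(w), cos(2 * w), sin(2 * w))
  for (f in daily_fields) {
    y <- series[[f]]
    miss <- is.na(y)
    if (!any(miss)) next
    fit <- stats::lm.fit(X[!miss, , drop = FALSE], y[!miss])
    pred <- X[miss, , drop = FALSE] %*% fit$coefficients
    if (startsWith(f, "rh")) pred <- pmin(pmax(pred, 0), 100)
    series[[f]][miss] <- as.numeric(pred)
  }
  series
}

#' Fill long missing runs by nearest-neighbor multivariate regression
#'
#' For a station with one or more missing runs of five days or longer, the
#' three geographically closest stations with complete records are located
#' by haversine distance; each daily field of the target is regressed on
#' the corresponding field of the three neighbors over the target's
#' non-missing days, and the regression fills the missing days. If fewer
#' than three complete stations lie within `max_dist_km`, the target is
#' rejected (returned with `rejected = TRUE`), not an error: rejection is a
#' normal QC outcome.
#'
#' @param target one station's daily data.frame (`date` + daily fields).
#' @param target_meta single-row metadata for the target (needs `latitude`,
#'   `longitude`).
#' @param candidates named list of candidate daily data.frames (aligned on
#'   the same dates as `target`), names = station ids.
#' @param candidate_meta metadata data.frame covering the candidates.
#' @param max_dist_km neighbor search radius (default 100 km).
#' @param n_neighbors number of predictor stations (default 3).
#' @return list with `series` (filled data.frame or NULL), `rejected`
#'   (logical), `reason`, `neighbors` (ids used), and `coefficients` (per
#'   field, the fitted regression coefficients).
#' @export
fill_long_gaps <- function(target, target_meta, candidates, candidate_meta,
                           max_dist_km = 100, n_neighbors = 3) {
  complete_ids <- names(candidates)[vapply(candidates, function(s)
    all(stats::complete.cases(s[, daily_fields])), logical(1))]
  if (length(complete_ids) > 0) {
    cm <- candidate_meta[match(complete_ids, candidate_meta$station_id), ]
    d <- haversine_km(target_meta$latitude, target_meta$longitude,
                      cm$latitude, cm$longitude)
    near <- complete_ids[d <= max_dist_km]
    d <- d[d <= max_dist_km]
  } else {
    near <- character(0)
    d <- numeric(0)
  }
  if (length(near) < n_neighbors) {
    return(list(series = NULL, rejected = TRUE,
                reason = sprintf(
                  "only %d complete stations within %g km (need %d)",
                  length(near), max_dist_km, n_neighbors),
                neighbors = character(0), coefficients = NULL))
  }
  nb <- near[order(d)][seq_len(n_neighbors)]
  coefs <- list()
  for (f in daily_fields) {
    y <- target[[f]]
    miss <- is.na(y)
    if (!any(miss)) next
    X <- cbind(1, do.call(cbind, lapply(candidates[nb], `[[`, f)))
    fit <- stats::lm.fit(X[!miss, , drop = FALSE], y[!miss])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # collinear neighbors contribute nothing extra
    pred <- X[miss, , drop = FALSE] %*% beta
    if (startsWith(f, "rh")) pred <- pmin(pmax(pred, 0), 100)
    target[[f]][miss] <- as.numeric(pred)
    coefs[[f]] <- stats::setNames(beta, c("(Intercept)", nb))
  }
  list(series = target, rejected = FALSE, reason = NA_character_,
       neighbors = nb, coefficients = coefs)
}

#' Lag-1 autocorrelation check for annual block maxima
#'
#' Computes the lag-1 sample autocorrelation and flags the series when
#' `|r1| > 2/sqrt(n)` (the usual white-noise band). The flag is reported,
#' not acted on: block maxima are examined for autocorrelation before GEV
#' analysis but not corrected.
#'
#' @param maxima numeric vector of annual block maxima (n >= 10).
#' @return list with `r1`, `flag`, `threshold` (`2/sqrt(n)`), `degenerate`
#'   (TRUE for a constant series, where r1 is undefined).
#' @export
check_autocorrelation <- function(maxima) {
  x <- maxima[!is.na(maxima)]
  n <- length(x)
  if (n < 10) stop("need at least 10 annual maxima")
  if (stats::sd(x) == 0) {
    return(list(r1 = NA_real_, flag = TRUE, threshold = 2 / sqrt(n),
                degenerate = TRUE))
  }
  r1 <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  list(r1 = r1, flag = abs(r1) > 2 / sqrt(n), threshold = 2 / sqrt(n),
       degenerate = FALSE)
}
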