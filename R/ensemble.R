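#' Select a warming-level window from a GMST series
#'
#' Finds the earliest 30-year period over which the mean global-mean
#' surface temperature anomaly first reaches the requested warming level.
#' Projections are structured around such warming-level windows rather
#' than common calendar periods, so ensemble members with different
#' climate sensitivities are sampled at a common climate state.
#'
#' @param gmst data.frame with `year` and `anomaly_c` (annual GMST anomaly,
#'   degC above preindustrial), consecutive years.
#' @param level warming level, degC (> 0).
#' @param window_years window length (default 30).
#' @return list of class `warming_window`: `reached` (logical), and when
#'   reached, `start_year`, `end_year`, `level`, `window_mean`.
#' @export
select_warming_window <- function(gmst, level, window_years = 30) {
  stopifnot(all(c("year", "anomaly_c") %in% names(gmst)), level > 0)
  yr <- gmst$year
  stopifnot(!is.unsorted(yr), all(diff(yr) == 1))
  n <- length(yr)
  if (n < window_years) {
    return(structure(list(reached = FALSE, level = level),
                     class = "warming_window"))
  }
  m <- roll_mean_start(gmst$anomaly_c, window_years)
  hit <- which(m >= level)
  if (length(hit) == 0) {
    return(structure(list(reached = FALSE, level = level),
                     class = "warming_window"))
  }
  i <- hit[1]
  structure(list(reached = TRUE, start_year = yr[i],
                 end_year = yr[i] + window_years - 1, level = level,
                 window_mean = m[i]),
            class = "warming_window")
}

#' @export
print.warming_window <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("Warming window %.2f degC: %d-%d (mean %.3f degC)\n",
                x$level, x$start_year, x$end_year, x$window_mean))
  } else {
    cat(sprintf("Warming level %.2f degC not reached\n", x$level))
  }
  invisible(x)
}

#' Pooled empirical return period from ensemble block maxima
#'
#' Treats each ensemble member's warming-window years as independent
#' samples of the same climate state and pools them: with `N` total
#' member-years and `k` years whose annual block maximum exceeds the
#' threshold, the return period is `N / k` years. When no year exceeds the
#' threshold the estimate is right-censored at the pool size (reported as
#' "> N years"). The estimate is invariant to member ordering and to how
#' the pool is partitioned into members.
#'
#' @param maxima pooled annual block maxima: a numeric vector, or a list of
#'   per-member vectors (flattened internally).
#' @param threshold event threshold (default 0, the compensability
#'   boundary).
#' @return list of class `pooled_return_period`: `return_period` (years; NA
#'   when censored), `censored`, `n_years`, `n_exceedances`.
#' @export
pooled_return_period <- function(maxima, threshold = 0) {
  if (is.list(maxima)) maxima <- unlist(maxima, use.names = FALSE)
  x <- maxima[!is.na(maxima)]
  n <- length(x)
  stopifnot(n >= 1)
  k <- sum(x > threshold)
  structure(list(
    return_period = if (k > 0) n / k else NA_real_,
    censored = k == 0, n_years = n, n_exceedances = k),
    class = "pooled_return_period")
}

#' @export
print.pooled_return_period <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Pooled return period: > %d years (no exceedance in pool)\n",
                x$n_years))
  } else {
    cat(sprintf("Pooled return period: %.3g years (%d/%d member-years)\n",
                x$return_period, x$n_exceedances, x$n_years))
  }
  invisible(x)
}

#' Pooled ensemble size in member-years
#'
#' The number of simulated years available per warming level when pooling
#' an ensemble: `n_members * window_years` (17 members x 30-year windows =
#' 510 member-years, about ten times the 50 years a 1970-2020 station
#' record provides).
#'
#' @param n_members ensemble size (default 17).
#' @param window_years warming-window length (default 30).
#' @return integer member-year count.
#' @export
pooled_sample_years <- function(n_members = 17, window_years = 30) {
  as.integer(n_members) * as.integer(window_years)
}

#' Ensemble return periods at a grid of warming levels
#'
#' For each warming level: per member, select the earliest 30-year window
#' reaching the level, reconstruct hourly series for those years, extract
#' annual windowed block maxima of the exceedance scalar, then pool all
#' member-years into an empirical return period. Members that never reach
#' a level are dropped from that level's pool.
#'
#' @param members list of members, each a list with `name`, `gmst`
#'   (data.frame `year`, `anomaly_c`) and `daily` (daily-stats data.frame
#'   with a `date` column).
#' @param thr `compensability_threshold`.
#' @param levels warming levels, degC.
#' @param window_hours exposure window for the block maxima (default 6).
#' @param window_years warming-window length (default 30).
#' @param threshold event threshold on the block maxima (default 0).
#' @return data.frame: `warming_level_c`, `return_period_years` (NA when
#'   censored), `censored`, `n_years`, `n_exceedances`, `n_members`.
#' @export
ensemble_return_periods <- function(members, thr,
                                    levels = seq(1, 3.5, by = 0.5),
                                    window_hours = 6, window_years = 30,
                                    threshold = 0) {
  rows <- lapply(levels, function(lv) {
    pool <- list()
    used <- 0L
    for (mb in members) {
      ww <- select_warming_window(mb$gmst, lv, window_years)
      if (!ww$reached) next
      yr <- as.integer(format(mb$daily$date, "%Y"))
      keep <- yr >= ww$start_year & yr <= ww$end_year
      sub <- mb$daily[keep, , drop = FALSE]
      hr <- reconstruct_hourly(sub)
      hr$exceedance <- exceedance_scalar(hr$temperature_c, hr$humidity_pct,
                                         thr)
      hr$year <- rep(yr[keep], each = 24)
      bm <- annual_block_maxima(hr, window_hours = window_hours)
      pool[[length(pool) + 1L]] <- bm$value
      used <- used + 1L
    }
    if (used == 0L) {
      return(data.frame(warming_level_c = lv, return_period_years = NA_real_,
                        censored = NA, n_years = 0L, n_exceedances = 0L,
                        n_members = 0L))
    }
    pr <- pooled_return_period(pool, threshold = threshold)
    data.frame(warming_level_c = lv,
               return_period_years = if (pr$censored) NA_real_ else
                 pr$return_period,
               censored = pr$censored, n_years = pr$n_years,
               n_exceedances = pr$n_exceedances, n_members = used)
  })
  do.call(rbind, rows)
}
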