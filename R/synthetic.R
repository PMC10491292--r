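#' Default configuration for the synthetic station generator
#'
#' Bundles every tunable of the synthetic world: the analysis period, the
#' climatology of the simulated region, the spatial layout of the station
#' cluster, the ground-truth extreme-value structure of the annual block
#' maxima, missing-data rates and inhomogeneity injections. Defaults
#' describe a hot subtropical cluster over a 50-year observational record
#' (1971-2020) with a warming GMST covariate, chosen so that annual maxima
#' of the 6-hour-mean exceedance scalar sit a few humidity points below
#' the compensability boundary at present-day warming and cross it at
#' higher warming levels.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical on re-run.
#' @param n_stations number of stations in the cluster.
#' @param years analysis years (annual block-maxima sample size).
#' @param center_lat,center_lon cluster center, degrees.
#' @param cluster_radius_km maximum station offset from the center.
#' @param corr_length_km e-folding length of inter-station correlation;
#'   stations at the center are perfectly correlated with the common
#'   signal.
#' @param base_temp annual-mean daily-mean temperature, degC.
#' @param seasonal_amp seasonal half-amplitude of daily-mean temperature,
#'   degC.
#' @param diurnal_amp_t,diurnal_amp_rh diurnal half-amplitudes (degC, RH
#'   percentage points).
#' @param temp_noise_sd day-to-day temperature noise, degC.
#' @param warming_sens local warming per degree of global warming
#'   (1 = local trend equals the global trend).
#' @param a1,a2,sigma,xi ground-truth GEV of the annual windowed block
#'   maxima: location `a1 + a2 * GMST_t` (humidity points), scale and
#'   shape.
#' @param summer_doy day-of-year range treated as the extreme season.
#' @param gmst_trend,gmst_noise_sd,gmst_baseline annual GMST anomaly:
#'   linear trend (degC/yr), white noise, and anomaly in the first year.
#' @param miss_short_rate,miss_long_rate per-day probability that a short
#'   (1-4 day) or long (5-15 day) missing run starts.
#' @param inhomogeneities data.frame (`station` index, `value` degC) of
#'   step-change injections; remaining stations receive small values below
#'   the 1 degC QC cutoff.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_stations = 6L,
                             years = 1971:2020,
                             center_lat = 27, center_lon = 51,
                             cluster_radius_km = 40,
                             corr_length_km = 60,
                             base_temp = 22, seasonal_amp = 8,
                             diurnal_amp_t = 4, diurnal_amp_rh = 10,
                             temp_noise_sd = 1.5,
                             warming_sens = 1.0,
                             a1 = -10, a2 = 3, sigma = 1.5, xi = -0.1,
                             summer_doy = c(152, 241),
                             gmst_trend = 0.018, gmst_noise_sd = 0.05,
                             gmst_baseline = 0.3,
                             miss_short_rate = 0.002,
                             miss_long_rate = 2e-5,
                             inhomogeneities = NULL) {
  cfg <- list(seed = seed, n_stations = as.integer(n_stations),
              years = years, center_lat = center_lat,
              center_lon = center_lon,
              cluster_radius_km = cluster_radius_km,
              corr_length_km = corr_length_km, base_temp = base_temp,
              seasonal_amp = seasonal_amp, diurnal_amp_t = diurnal_amp_t,
              diurnal_amp_rh = diurnal_amp_rh,
              temp_noise_sd = temp_noise_sd, warming_sens = warming_sens,
              a1 = a1, a2 = a2, sigma = sigma, xi = xi,
              summer_doy = summer_doy, gmst_trend = gmst_trend,
              gmst_noise_sd = gmst_noise_sd,
              gmst_baseline = gmst_baseline,
              miss_short_rate = miss_short_rate,
              miss_long_rate = miss_long_rate,
              inhomogeneities = inhomogeneities)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_stations >= 1, length(cfg$years) >= 1,
            cfg$sigma > 0,
            cfg$miss_short_rate >= 0, cfg$miss_short_rate <= 1,
            cfg$miss_long_rate >= 0, cfg$miss_long_rate <= 1,
            cfg$corr_length_km > 0, cfg$diurnal_amp_rh >= 0,
            cfg$summer_doy[1] < cfg$summer_doy[2])
  invisible(cfg)
}

# The quadratic used as ground truth for the compensability boundary in
# all synthetic worlds (a synthetic stand-in; the laboratory calibration
# values are not published in numeric form).
synthetic_truth_coefficients <- function() {
  c(c2 = -0.1, c1 = 4, c0 = 51.6)
}

#' Generate an annual GMST anomaly series
#'
#' Linear warming trend plus white noise:
#' `anomaly(year) = baseline + trend * (year - years[1]) + N(0, noise_sd)`.
#'
#' @param years vector of calendar years.
#' @param trend warming trend, degC per year.
#' @param noise_sd white-noise standard deviation, degC.
#' @param baseline anomaly in the first year, degC above preindustrial.
#' @param seed optional seed; NULL uses the current RNG stream.
#' @return data.frame with `year` and `anomaly_c`.
#' @export
generate_gmst <- function(years, trend = 0.018, noise_sd = 0.05,
                          baseline = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anom <- baseline + trend * (years - years[1])
  if (noise_sd > 0) anom <- anom + stats::rnorm(length(years), 0, noise_sd)
  data.frame(year = as.integer(years), anomaly_c = anom)
}

#' Generate synthetic compensability calibration points
#'
#' Six points on a known downward-opening quadratic in temperature-humidity
#' space plus optional Gaussian noise, emulating the shape of averaged
#' laboratory compensability limits: three humid-warm points and three
#' hot-dry points, monotone decreasing in humidity as temperature rises.
#' These are synthetic stand-ins with a recorded generating curve, not
#' laboratory values.
#'
#' @param seed optional RNG seed.
#' @param noise_sd humidity noise, percentage points (0 puts the points
#'   exactly on the curve).
#' @return data.frame `temperature_c`, `humidity_pct`, `label`, with the
#'   generating coefficients in `attr(, "truth")`.
#' @export
generate_calibration_points <- function(seed = NULL, noise_sd = 0.8) {
  if (!is.null(seed)) set.seed(seed)
  cf <- synthetic_truth_coefficients()
  tt <- c(36, 38, 40, 42, 44, 46)
  hh <- cf["c2"] * tt^2 + cf["c1"] * tt + cf["c0"]
  if (noise_sd > 0) hh <- hh + stats::rnorm(6, 0, noise_sd)
  pts <- data.frame(
    temperature_c = tt,
    humidity_pct = pmin(pmax(as.numeric(hh), 0), 100),
    label = rep(c("high-humidity", "high-heat"), each = 3),
    stringsAsFactors = FALSE)
  attr(pts, "truth") <- cf
  pts
}

# Invert GEV max-stability: per-day parameters (mu0, sigma0) such that the
# maximum of n_days iid GEV(mu0, sigma0, xi) draws is GEV(a1, sigma, xi).
per_day_gev_params <- function(a1, sigma, xi, n_days, tol = 1e-6) {
  if (abs(xi) < tol) {
    sigma0 <- sigma
    mu0 <- a1 - sigma0 * log(n_days)
  } else {
    sigma0 <- sigma * n_days^(-xi)
    mu0 <- a1 - sigma0 * (n_days^xi - 1) / xi
  }
  c(mu0 = mu0, sigma0 = sigma0)
}

# Largest within-day window mean of (rh_anomaly(h) - q(T(h))) for each day,
# mirroring the hourly reconstruction: T(h) = t_mean + amp_t*cos(.-15),
# rh_anomaly(h) = amp_rh*cos(.-3). Returns a vector over days.
day_window_offset <- function(t_mean, amp_t, amp_rh, cf, window_hours = 6,
                              t_peak_hour = 15) {
  h <- 0:23
  cos_t <- cos(2 * pi * (h - t_peak_hour) / 24)
  cos_rh <- cos(2 * pi * (h - t_peak_hour - 12) / 24)
  n <- length(t_mean)
  # n x 24 hourly matrix of rh_anom - q(T)
  tm <- outer(t_mean, cos_t * amp_t, `+`)
  m <- -(cf["c2"] * tm^2 + cf["c1"] * tm + cf["c0"]) +
    matrix(amp_rh * cos_rh, n, 24, byrow = TRUE)
  best <- rep(-Inf, n)
  for (s in 1:(24 - window_hours + 1)) {
    best <- pmax(best, rowMeans(m[, s:(s + window_hours - 1), drop = FALSE]))
  }
  best
}

# Inject NA runs. rate = per-day probability a run starts; run lengths
# sampled uniformly from len_range.
inject_missing_runs <- function(n, rate, len_range) {
  miss <- rep(FALSE, n)
  if (rate <= 0) return(miss)
  starts <- which(stats::runif(n) < rate)
  for (s in starts) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    miss[s:min(n, s + len - 1)] <- TRUE
  }
  miss
}

# Daily stats for one station given target daily block-max exceedances.
# The daily mean humidity is solved so that the best within-day
# window-mean exceedance of the reconstructed hourly series equals the
# target e_day exactly (up to clipping at the physical RH bounds).
station_daily_stats <- function(dates, t_mean, e_day, cfg, cf) {
  amp_t <- cfg$diurnal_amp_t
  amp_rh <- cfg$diurnal_amp_rh
  k <- day_window_offset(t_mean, amp_t, amp_rh, cf)
  rh_mean <- e_day - k
  rh_mean <- pmin(pmax(rh_mean, amp_rh + 0.5), 100 - amp_rh - 0.5)
  data.frame(date = dates,
             t_max = t_mean + amp_t, t_min = t_mean - amp_t,
             t_mean = t_mean,
             rh_max = rh_mean + amp_rh, rh_min = rh_mean - amp_rh,
             rh_mean = rh_mean)
}

# Core day-level generator shared by the station-network and ensemble
# branches. gmst_by_day: anomaly for each date's year. z_common: list of
# two N(0,1) vectors over days shared within a cluster; rho: this
# station's loading on them.
gen_station_days <- function(dates, gmst_by_day, cfg, cf, z_common, rho) {
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  seas <- cos(2 * pi * (doy - 196) / 365.25)
  mix <- function(zc) rho * zc + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  z_e <- mix(z_common$e)
  z_t <- mix(z_common$t)
  t_mean <- cfg$base_temp + cfg$seasonal_amp * seas +
    cfg$warming_sens * gmst_by_day + cfg$temp_noise_sd * z_t
  summer <- doy >= cfg$summer_doy[1] & doy <= cfg$summer_doy[2]
  pd <- per_day_gev_params(cfg$a1, cfg$sigma, cfg$xi,
                           cfg$summer_doy[2] - cfg$summer_doy[1] + 1)
  e_day <- -35 + 8 * seas + 1.5 * z_e
  u <- stats::pnorm(z_e[summer])
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  e_day[summer] <- cfg$a2 * gmst_by_day[summer] +
    gev_quantile(u, pd["mu0"], pd["sigma0"], cfg$xi)
  station_daily_stats(dates, t_mean, e_day, cfg, cf)
}

#' Generate a synthetic station network with known ground truth
#'
#' Builds a cluster of weather stations whose annual windowed block maxima
#' of the exceedance scalar follow, by construction, a generalized
#' extreme value distribution with location `a1 + a2 * GMST_t` and the
#' configured scale and shape: daily peak exceedances of the extreme
#' season are drawn iid GEV per day (max-stability then gives the annual
#' law exactly), and the daily humidity statistics are solved so the
#' reconstructed hourly series realizes those targets through the actual
#' diurnal and windowing machinery. Neighboring stations share a common
#' daily signal (Gaussian copula with loading `exp(-d/corr_length)`), so
#' regression-based gap filling is learnable. Missing runs and temperature
#' inhomogeneities are injected per the configuration.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `daily` (long data.frame of station-days), `meta`
#'   (station metadata), `gmst` (annual anomaly series), `calibration`
#'   (six synthetic calibration points) and `truth` (generating
#'   parameters: threshold coefficients, GEV structure, per-station
#'   loadings).
#' @export
generate_station_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_synthetic_config(cfg)
  set.seed(cfg$seed)
  cf <- synthetic_truth_coefficients()
  years <- cfg$years
  gmst <- generate_gmst(years, cfg$gmst_trend, cfg$gmst_noise_sd,
                        cfg$gmst_baseline, seed = NULL)
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  yr_day <- as.integer(format(dates, "%Y"))
  g_day <- gmst$anomaly_c[match(yr_day, gmst$year)]
  n_days <- length(dates)

  # station placement: station 1 at the cluster center
  ns <- cfg$n_stations
  r <- c(0, stats::runif(ns - 1, 0, cfg$cluster_radius_km))
  theta <- c(0, stats::runif(ns - 1, 0, 2 * pi))
  lat <- cfg$center_lat + r * sin(theta) / 111.32
  lon <- cfg$center_lon + r * cos(theta) /
    (111.32 * cos(cfg$center_lat * pi / 180))
  d_center <- haversine_km(cfg$center_lat, cfg$center_lon, lat, lon)
  rho <- exp(-d_center / cfg$corr_length_km)

  z_common <- list(e = stats::rnorm(n_days), t = stats::rnorm(n_days))
  ids <- sprintf("SYN%03d", seq_len(ns))

  inh <- rep(NA_real_, ns)
  inh_small <- stats::runif(ns, 0, 0.4)
  inh[] <- inh_small
  if (!is.null(cfg$inhomogeneities)) {
    inh[cfg$inhomogeneities$station] <- cfg$inhomogeneities$value
  }

  daily <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- gen_station_days(dates, g_day, cfg, cf, z_common, rho[i])
    # inhomogeneity: step change in the temperature fields mid-record
    if (inh[i] > 0.5) {
      brk <- dates[n_days %/% 2]
      late <- s$date > brk
      for (f in c("t_max", "t_min", "t_mean")) {
        s[[f]][late] <- s[[f]][late] + inh[i]
      }
    }
    miss <- inject_missing_runs(n_days, cfg$miss_short_rate, c(1, 4)) |
      inject_missing_runs(n_days, cfg$miss_long_rate, c(5, 15))
    for (f in daily_fields) s[[f]][miss] <- NA_real_
    s <- cbind(station_id = ids[i], s, stringsAsFactors = FALSE)
    daily[[i]] <- s
  }

  meta <- data.frame(
    station_id = ids, latitude = lat, longitude = lon,
    elevation_m = 10, is_land = TRUE,
    record_start = dates[1], temp_inhomogeneity = inh,
    stringsAsFactors = FALSE)

  calibration <- generate_calibration_points(seed = NULL)

  list(daily = do.call(rbind, daily), meta = meta, gmst = gmst,
       calibration = calibration,
       truth = list(threshold = cf, a1 = cfg$a1, a2 = cfg$a2,
                    sigma = cfg$sigma, xi = cfg$xi, rho = rho,
                    config = cfg))
}

#' Generate a synthetic climate-model ensemble
#'
#' Each member carries an annual GMST anomaly series over a long
#' simulation span with its own warming rate (emulating differing climate
#' sensitivities) and daily statistics at one location generated with the
#' same machinery as the station network, so that conditional on GMST all
#' members share one climate-state distribution per warming level.
#'
#' @param cfg a [synthetic_config()]; its GEV ground truth and climatology
#'   apply to every member.
#' @param n_members ensemble size (default 17).
#' @param sim_years simulation span (default 1950:2100).
#' @param sens_range range of member warming rates as multiples of a
#'   0.025 degC/yr reference ramp.
#' @return list of members, each a list with `name`, `gmst`, `daily`, plus
#'   attribute `truth`.
#' @export
generate_ensemble <- function(cfg, n_members = 17, sim_years = 1950:2100,
                              sens_range = c(1.0, 1.4)) {
  stopifnot(inherits(cfg, "synthetic_config"), n_members >= 1)
  set.seed(cfg$seed)
  cf <- synthetic_truth_coefficients()
  dates <- seq(as.Date(sprintf("%d-01-01", sim_years[1])),
               as.Date(sprintf("%d-12-31", sim_years[length(sim_years)])),
               by = "day")
  yr_day <- as.integer(format(dates, "%Y"))
  n_days <- length(dates)
  members <- vector("list", n_members)
  sens <- stats::runif(n_members, sens_range[1], sens_range[2])
  for (m in seq_len(n_members)) {
    gmst <- generate_gmst(sim_years, trend = 0.025 * sens[m],
                          noise_sd = cfg$gmst_noise_sd,
                          baseline = cfg$gmst_baseline, seed = NULL)
    g_day <- gmst$anomaly_c[match(yr_day, gmst$year)]
    z <- list(e = stats::rnorm(n_days), t = stats::rnorm(n_days))
    s <- gen_station_days(dates, g_day, cfg, cf, z, rho = 1)
    members[[m]] <- list(name = sprintf("SYN-ESM-%02d", m), gmst = gmst,
                         daily = s, sensitivity = sens[m])
  }
  attr(members, "truth") <- list(threshold = cf, a1 = cfg$a1, a2 = cfg$a2,
                                 sigma = cfg$sigma, xi = cfg$xi,
                                 sensitivities = sens)
  members
}
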