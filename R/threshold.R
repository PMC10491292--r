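#' Fit the compensability threshold curve
#'
#' Fits a quadratic curve `q(T) = c2*T^2 + c1*T + c0` through calibration
#' points in dry-bulb temperature / relative humidity space by ordinary
#' least squares on the humidity axis. States above the curve are
#' noncompensable: a healthy human cannot maintain stable core temperature
#' there without external cooling.
#'
#' @param points data.frame with columns `temperature_c` (dry-bulb, degrees
#'   Celsius) and `humidity_pct` (relative humidity, percent). An optional
#'   `label` column is carried through untouched.
#' @return An object of class `compensability_threshold`: list with
#'   coefficients `c2`, `c1`, `c0`, the goodness of fit `r_squared`
#'   (1 - SS_res/SS_tot), and `fit_domain`, the temperature range spanned by
#'   the calibration points.
#' @details At least three points with three distinct temperatures are
#'   required; fewer make the quadratic design degenerate. When all
#'   calibration humidities are equal, `r_squared` is defined as 1 if the
#'   residuals are all (numerically) zero and 0 otherwise.
#' @export
#' @examples
#' pts <- data.frame(temperature_c = c(36, 40, 44),
#'                   humidity_pct  = c(66, 51.6, 29.2))
#' thr <- fit_threshold(pts)
#' threshold_humidity(thr, 38)
fit_threshold <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("temperature_c", "humidity_pct") %in% names(points)))
  tt <- points$temperature_c
  hh <- points$humidity_pct
  if (any(!is.finite(tt)) || any(!is.finite(hh))) {
    stop("calibration points must be finite")
  }
  if (any(hh < 0 | hh > 100)) {
    stop("calibration humidities must lie in [0, 100]")
  }
  if (length(unique(tt)) < 3) {
    stop("degenerate design: need at least 3 distinct calibration temperatures")
  }
  fit <- stats::lm(hh ~ tt + I(tt^2))
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((hh - mean(hh))^2)
  r2 <- if (ss_tot > .Machine$double.eps * max(1, sum(hh^2))) {
    1 - ss_res / ss_tot
  } else {
    as.numeric(ss_res < 1e-10)
  }
  structure(
    list(c2 = unname(cf[3]), c1 = unname(cf[2]), c0 = unname(cf[1]),
         r_squared = r2, fit_domain = range(tt)),
    class = "compensability_threshold"
  )
}

#' Construct a compensability threshold from known coefficients
#'
#' @param c2,c1,c0 quadratic coefficients mapping temperature (degrees C) to
#'   the critical relative humidity (percent).
#' @param r_squared goodness of fit, if known.
#' @param fit_domain temperature range (degrees C) over which the curve was
#'   calibrated.
#' @return A `compensability_threshold` object.
#' @export
compensability_threshold <- function(c2, c1, c0, r_squared = NA_real_,
                                     fit_domain = c(NA_real_, NA_real_)) {
  stopifnot(is.finite(c2), is.finite(c1), is.finite(c0))
  structure(
    list(c2 = c2, c1 = c1, c0 = c0, r_squared = r_squared,
         fit_domain = fit_domain),
    class = "compensability_threshold"
  )
}

#' @export
print.compensability_threshold <- function(x, ...) {
  cat(sprintf("Compensability threshold: q(T) = %.4g*T^2 + %.4g*T + %.4g\n",
              x$c2, x$c1, x$c0))
  cat(sprintf("  R^2 = %s, fit domain [%s, %s] degC\n",
              format(x$r_squared, digits = 4),
              format(x$fit_domain[1]), format(x$fit_domain[2])))
  invisible(x)
}

#' Critical relative humidity at a given temperature
#'
#' Evaluates the threshold curve: the relative humidity above which a state
#' at dry-bulb temperature `temperature` is noncompensable.
#'
#' @param thr a `compensability_threshold`.
#' @param temperature dry-bulb temperature(s), degrees C.
#' @return Critical relative humidity, percent (not clipped to [0, 100]).
#' @export
threshold_humidity <- function(thr, temperature) {
  stopifnot(inherits(thr, "compensability_threshold"))
  thr$c2 * temperature^2 + thr$c1 * temperature + thr$c0
}

#' Signed exceedance scalar of a temperature-humidity state
#'
#' The vertical signed distance of a state from the threshold curve:
#' `humidity - q(temperature)`, in relative-humidity percentage points.
#' Zero means the state lies on the curve, negative values are compensable,
#' positive values noncompensable.
#'
#' @param temperature dry-bulb temperature(s), degrees C.
#' @param humidity relative humidity, percent; recycled against temperature.
#' @param thr a `compensability_threshold`.
#' @return Numeric vector of signed exceedances.
#' @export
exceedance_scalar <- function(temperature, humidity, thr) {
  humidity - threshold_humidity(thr, temperature)
}

#' Binarize an exceedance scalar
#'
#' Maps the signed exceedance scalar to a compensability flag:
#' 1 for noncompensable (scalar strictly greater than 0), 0 for compensable.
#' The boundary (scalar exactly 0, a state on the curve) is classified
#' compensable.
#'
#' @param scalar numeric vector of exceedance scalars; NA propagates.
#' @return Integer vector of 0/1 flags.
#' @export
binarize <- function(scalar) {
  out <- rep(NA_integer_, length(scalar))
  ok <- !is.na(scalar)
  out[ok] <- as.integer(scalar[ok] > 0)
  out
}

# Saturation vapor pressure over water (hPa), Bolton-style Magnus formula.
saturation_vp <- function(temperature) {
  6.112 * exp(17.67 * temperature / (temperature + 243.5))
}

#' Wet-bulb temperature by iterative psychrometric solution
#'
#' Solves the psychrometric balance
#' `e = es(Tw) - A * p * (T - Tw)` for the wet-bulb temperature `Tw`,
#' where `es` is the Magnus saturation vapor pressure and
#' `A = 6.62e-4 K^-1` is the psychrometer coefficient. Newton iteration
#' starting from the dry-bulb temperature. A diagnostic utility for
#' comparing states against wet-bulb isopleths (e.g. the proposed 35 degC
#' survivability limit); it feeds no pipeline stage.
#'
#' @param temperature dry-bulb temperature, degrees C.
#' @param humidity relative humidity, percent, in (0, 100].
#' @param pressure air pressure, hPa; default standard atmosphere 1013.25.
#' @param tol convergence tolerance on Tw, degrees C.
#' @param max_iter maximum Newton iterations before a numerical error is
#'   raised.
#' @return Wet-bulb temperature(s), degrees C. Always less than or equal to
#'   the dry-bulb temperature, with equality at saturation.
#' @export
wet_bulb <- function(temperature, humidity, pressure = 1013.25,
                     tol = 1e-8, max_iter = 100) {
  stopifnot(all(humidity > 0), all(humidity <= 100), all(pressure > 0))
  n <- max(length(temperature), length(humidity), length(pressure))
  temperature <- rep_len(temperature, n)
  humidity <- rep_len(humidity, n)
  pressure <- rep_len(pressure, n)
  a <- 6.62e-4
  e <- humidity / 100 * saturation_vp(temperature)
  tw <- temperature  # saturation start; f(T) >= 0 and f is increasing
  for (iter in seq_len(max_iter)) {
    es_tw <- saturation_vp(tw)
    f <- es_tw - a * pressure * (temperature - tw) - e
    if (all(abs(f) < 1e-12) ) break
    des <- es_tw * 17.67 * 243.5 / (tw + 243.5)^2
    step <- f / (des + a * pressure)
    tw <- tw - step
    if (all(abs(step) < tol)) break
    if (iter == max_iter) {
      stop("wet_bulb: Newton iteration did not converge")
    }
  }
  pmin(tw, temperature)
}

#' Hours of noncompensable exposure to reach the lethal core temperature
#'
#' Under sustained noncompensable heat the core temperature of a healthy,
#' non-heat-adapted human rises at roughly 1 degree C per hour; starting
#' from a normal core temperature of 37 degC, the 43 degC lethal limit is
#' reached after six hours. This arithmetic motivates the default 6-hour
#' exposure window used throughout the package.
#'
#' @param core_start normal core temperature, degC (default 37).
#' @param core_lethal lethal core temperature, degC (default 43).
#' @param rate_per_hour core warming rate under noncompensable conditions,
#'   degC per hour (default 1).
#' @return Exposure duration in hours.
#' @export
lethal_exposure_hours <- function(core_start = 37, core_lethal = 43,
                                  rate_per_hour = 1) {
  stopifnot(core_lethal > core_start, rate_per_hour > 0)
  (core_lethal - core_start) / rate_per_hour
}

#' Export / import a threshold as a JSON text record
#'
#' @param thr a `compensability_threshold`.
#' @param path file path for the JSON record.
#' @return `write_threshold` returns `path` invisibly; `read_threshold`
#'   returns the reconstructed `compensability_threshold`.
#' @export
write_threshold <- function(thr, path) {
  stopifnot(inherits(thr, "compensability_threshold"))
  jsonlite::write_json(unclass(thr), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold
#' @export
read_threshold <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  compensability_threshold(x$c2, x$c1, x$c0,
                           r_squared = x$r_squared,
                           fit_domain = as.numeric(x$fit_domain))
}
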