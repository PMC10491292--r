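# Shared fixtures, all built in code.

# Ground-truth threshold used by the synthetic generator.
truth_threshold <- function() {
  cf <- noncompheat:::synthetic_truth_coefficients()
  compensability_threshold(cf[["c2"]], cf[["c1"]], cf[["c0"]],
                           r_squared = 1, fit_domain = c(36, 46))
}

# Deterministic one-station daily series over `years`: fixed seasonal
# temperature cycle and a slowly rising mean humidity, so the late-era
# exceedance peak always beats the early-era peak.
make_clean_series <- function(years = 1971:2020, rh_base = 40,
                              rh_trend_per_year = 0.05, spike_dates = NULL,
                              spike_rh = 95) {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])),
               by = "day")
  doy <- as.numeric(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  tm <- 22 + 8 * cos(2 * pi * (doy - 196) / 365.25)
  rh <- rh_base + rh_trend_per_year * (yr - years[1])
  if (!is.null(spike_dates)) rh[dates %in% spike_dates] <- spike_rh
  data.frame(date = dates,
             t_max = tm + 4, t_min = tm - 4, t_mean = tm,
             rh_max = pmin(rh + 10, 100), rh_min = pmax(rh - 10, 0),
             rh_mean = rh)
}

# Ten-station QC fixture designed so each filter fires a known number of
# times: 1 ocean, 1 polar, 2 over-missing, 1 early-record maximum,
# 1 strong inhomogeneity, 4 clean.
make_qc_fixture <- function() {
  ids <- sprintf("FIX%02d", 1:10)
  lat <- c(27, 27.1, 26.9, 27.2, 27.05, 65, 27.15, 26.95, 27.08, 26.85)
  land <- rep(TRUE, 10)
  land[5] <- FALSE                      # ocean station
  inh <- rep(0.2, 10)
  inh[7] <- 1.5                         # inhomogeneous station
  series <- list()
  for (i in 1:10) {
    s <- make_clean_series()
    if (i %in% c(2, 3)) {               # over-missing: drop 60% of days
      drop <- seq_len(nrow(s)) %% 5 %in% c(0, 1, 2)
      for (f in noncompheat:::daily_fields) s[[f]][drop] <- NA_real_
    }
    if (i == 9) {                       # early-era extreme beats late era
      s <- make_clean_series(spike_dates = as.Date("1980-07-15"))
    }
    series[[ids[i]]] <- cbind(station_id = ids[i], s,
                              stringsAsFactors = FALSE)
  }
  meta <- data.frame(station_id = ids, latitude = lat,
                     longitude = 51 + seq(0, 0.9, by = 0.1),
                     elevation_m = 10, is_land = land,
                     record_start = as.Date("1971-01-01"),
                     temp_inhomogeneity = inh, stringsAsFactors = FALSE)
  list(meta = meta, daily = do.call(rbind, series))
}
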