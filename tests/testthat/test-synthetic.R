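test_that("GMST generation honors trend, noise and determinism contracts", {
  flat <- generate_gmst(2000:2049, trend = 0, noise_sd = 0, baseline = 0.5)
  expect_equal(flat$anomaly_c, rep(0.5, 50))
  ramp <- generate_gmst(2000:2049, trend = 0.02, noise_sd = 0, baseline = 0)
  expect_equal(ramp$anomaly_c[50] - ramp$anomaly_c[1], 0.98)
  expect_equal(diff(range(ramp$anomaly_c)), 0.02 * 49)
  a <- generate_gmst(1971:2020, seed = 11)
  b <- generate_gmst(1971:2020, seed = 11)
  expect_identical(a, b)
})

test_that("noise-free calibration points reproduce the generating quadratic", {
  pts <- generate_calibration_points(noise_sd = 0)
  thr <- fit_threshold(pts)
  truth <- attr(pts, "truth")
  expect_equal(thr$c2, unname(truth["c2"]), tolerance = 1e-8)
  expect_equal(thr$c1, unname(truth["c1"]), tolerance = 1e-7)
  expect_equal(thr$c0, unname(truth["c0"]), tolerance = 1e-6)
  expect_equal(thr$r_squared, 1, tolerance = 1e-10)
})

test_that("default-noise calibration points fit tightly and slope downward", {
  set.seed(801)
  r2 <- replicate(50, fit_threshold(generate_calibration_points())$r_squared)
  expect_true(all(r2 > 0.95))
  pts <- generate_calibration_points(seed = 802)
  expect_true(all(diff(pts$humidity_pct[order(pts$temperature_c)]) < 0))
  expect_equal(pts$label, rep(c("high-humidity", "high-heat"), each = 3))
})

test_that("zero missingness yields complete records; rates inject gaps", {
  cfg <- synthetic_config(seed = 21, n_stations = 2, years = 1996:2000,
                          miss_short_rate = 0, miss_long_rate = 0)
  net <- generate_station_network(cfg)
  expect_false(anyNA(net$daily[, noncompheat:::daily_fields]))
  cfg2 <- synthetic_config(seed = 21, n_stations = 2, years = 1996:2000,
                           miss_short_rate = 0.01, miss_long_rate = 0.002)
  net2 <- generate_station_network(cfg2)
  expect_true(anyNA(net2$daily$t_mean))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 22, n_stations = 3, years = 1996:2000)
  a <- generate_station_network(cfg)
  b <- generate_station_network(cfg)
  expect_identical(a$daily, b$daily)
  expect_identical(a$meta, b$meta)
  expect_identical(a$gmst, b$gmst)
})

test_that("co-located stations are perfectly correlated copies", {
  cfg <- synthetic_config(seed = 23, n_stations = 2, years = 1996:1998,
                          cluster_radius_km = 0, miss_short_rate = 0,
                          miss_long_rate = 0)
  net <- generate_station_network(cfg)
  s1 <- net$daily[net$daily$station_id == "SYN001",
                  noncompheat:::daily_fields]
  s2 <- net$daily[net$daily$station_id == "SYN002",
                  noncompheat:::daily_fields]
  expect_equal(unname(as.matrix(s1)), unname(as.matrix(s2)),
               tolerance = 1e-12)
})

test_that("daily physical invariants hold in generated records", {
  cfg <- synthetic_config(seed = 24, n_stations = 2, years = 1996:2000)
  d <- generate_station_network(cfg)$daily
  ok <- stats::complete.cases(d[, noncompheat:::daily_fields])
  d <- d[ok, ]
  expect_true(all(d$t_min <= d$t_mean & d$t_mean <= d$t_max))
  expect_true(all(d$rh_min >= 0 & d$rh_max <= 100))
  expect_true(all(d$rh_min <= d$rh_mean & d$rh_mean <= d$rh_max))
})

test_that("clean block maxima recover the generating GEV slope", {
  # band frozen from a 40-replicate spread of single-station fits
  # (mean 3.08, sd 0.81); bounds are mean +/- 4 sd around the truth
  cfg <- synthetic_config(seed = 25, n_stations = 1, miss_short_rate = 0,
                          miss_long_rate = 0)
  net <- generate_station_network(cfg)
  thr <- truth_threshold()
  s <- net$daily
  hr <- reconstruct_hourly(s)
  hr$exceedance <- exceedance_scalar(hr$temperature_c, hr$humidity_pct, thr)
  hr$year <- rep(as.integer(format(s$date, "%Y")), each = 24)
  bm <- annual_block_maxima(hr, net$gmst)
  fit <- fit_gev_nonstationary(bm$value, bm$covariate)
  expect_lt(abs(fit$a2 - cfg$a2), 4 * 0.82)
  # stationary scale/shape should be in the right regime too
  expect_lt(abs(fit$sigma - cfg$sigma), 1)
  expect_lt(fit$xi, 0.35)
})

test_that("full-chain return periods agree with the generating model", {
  # analytic truth at 3.5 degC warming: mu = a1 + 3.5*a2. Per-replicate
  # log10 return-period errors are heavy-tailed (the 50-year shape
  # estimate occasionally censors the extrapolation), so the check is on
  # the median of five replicates; the band is 3x the 40-replicate
  # single-fit log10 spread (sd 0.40)
  thr <- truth_threshold()
  rp_est <- vapply(101:105, function(sd0) {
    cfg <- synthetic_config(seed = sd0, n_stations = 1,
                            miss_short_rate = 0, miss_long_rate = 0)
    net <- generate_station_network(cfg)
    s <- net$daily
    hr <- reconstruct_hourly(s)
    hr$exceedance <- exceedance_scalar(hr$temperature_c, hr$humidity_pct,
                                       thr)
    hr$year <- rep(as.integer(format(s$date, "%Y")), each = 24)
    bm <- annual_block_maxima(hr, net$gmst)
    fit <- fit_gev_nonstationary(bm$value, bm$covariate)
    return_period(fit, 3.5)$return_period_years
  }, numeric(1))
  cfg <- synthetic_config(seed = 101)
  truth_model <- structure(list(kind = "nonstationary", a1 = cfg$a1,
                                a2 = cfg$a2, sigma = cfg$sigma, xi = cfg$xi),
                           class = "gev_model")
  rp_true <- return_period(truth_model, 3.5)$return_period_years
  expect_lt(abs(median(log10(rp_est)) - log10(rp_true)), 3 * 0.40)
})
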