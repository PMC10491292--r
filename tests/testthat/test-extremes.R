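test_that("the GEV cdf matches its closed forms and support behavior", {
  expect_equal(gev_cdf(10, 10, 2, 0), exp(-1))
  # bounded right tail: above the finite upper endpoint the cdf is 1
  up <- 10 - 2 / (-0.2)  # mu - sigma/xi = 20
  expect_equal(gev_cdf(up + 1, 10, 2, -0.2), 1)
  expect_equal(gev_cdf(up + 100, 10, 2, -0.2), 1)
  # heavy tail: below the lower endpoint the cdf is 0
  expect_equal(gev_cdf(-100, 10, 2, 0.2), 0)
  expect_error(gev_cdf(0, 0, -1, 0), "sigma")
})

test_that("cdf increments equal numerical quadrature of the density", {
  dgev <- function(x, mu, sigma, xi) {  # independent density formula
    z <- (x - mu) / sigma
    if (abs(xi) < 1e-12) {
      exp(-z - exp(-z)) / sigma
    } else {
      t <- 1 + xi * z
      ifelse(t > 0, t^(-1 - 1 / xi) * exp(-t^(-1 / xi)) / sigma, 0)
    }
  }
  for (xi in c(-0.2, 0, 0.15)) {
    grid <- seq(6, 18, by = 2)
    for (i in seq_len(length(grid) - 1)) {
      quad <- integrate(dgev, grid[i], grid[i + 1], mu = 10, sigma = 2,
                        xi = xi, rel.tol = 1e-12)$value
      inc <- gev_cdf(grid[i + 1], 10, 2, xi) - gev_cdf(grid[i], 10, 2, xi)
      expect_equal(inc, quad, tolerance = 1e-8)
    }
  }
})

test_that("the Gumbel limiting form is continuous at tiny shape", {
  x <- seq(0, 30, by = 0.5)
  gumbel <- exp(-exp(-(x - 10) / 2))
  expect_lt(max(abs(gev_cdf(x, 10, 2, 1e-8) - gumbel)), 1e-6)
  # just above the switch tolerance the two branches still agree closely
  expect_lt(max(abs(gev_cdf(x, 10, 2, 1e-5, tol = 1e-6) - gumbel)), 1e-4)
})

test_that("return levels round-trip through the cdf", {
  m <- c(2, 10, 100, 1000)
  for (xi in c(-0.15, 0, 0.1)) {
    x_m <- gev_quantile(1 - 1 / m, 8, 1.5, xi)
    expect_equal(gev_cdf(x_m, 8, 1.5, xi), 1 - 1 / m, tolerance = 1e-12)
  }
})

test_that("a large Gumbel sample is recovered by the stationary fit", {
  set.seed(601)
  x <- gev_rand(1000, 10, 2, 0)
  fit <- fit_gev_stationary(x)
  expect_lt(abs(fit$mu - 10), 0.3)
  expect_lt(abs(fit$sigma - 2), 0.3)
  expect_lt(abs(fit$xi), 0.1)
  # MLE optimality: beats the generating parameters
  expect_gte(fit$loglik, -noncompheat:::gev_nll(x, 10, 2, 0) - 1e-6)
})

test_that("samples below the minimum size are refused", {
  expect_error(fit_gev_stationary(rnorm(5)), "at least 20")
  expect_silent(fit_gev_stationary(gev_rand(8, 0, 1, 0), n_min = 5))
})

test_that("the fitted-parameter KS screen passes distribution-true samples", {
  set.seed(602)
  pass <- replicate(200, {
    x <- gev_rand(200, 10, 2, -0.1)
    ks_test(x, fit_gev_stationary(x))$pass
  })
  expect_gte(mean(pass), 0.9)
})

test_that("the KS screen rejects gross misfits and accepts exact quantiles", {
  set.seed(603)
  model <- fit_gev_stationary(gev_rand(200, 0, 1, 0))
  far <- rnorm(100, 50, 1)
  expect_false(ks_test(far, model)$pass)
  # maxima placed at the model quantiles of plotting positions
  n <- 100
  q <- gev_quantile((seq_len(n) - 0.5) / n, model$mu, model$sigma, model$xi)
  expect_lt(ks_test(q, model)$statistic, 1 / n)
})

test_that("trendless data yield a near-zero slope and nested log-likelihoods", {
  set.seed(604)
  tt <- seq(0.3, 1.2, length.out = 200)
  x <- gev_rand(200, 5, 1, -0.1)
  st <- fit_gev_stationary(x)
  ns <- fit_gev_nonstationary(x, tt)
  expect_lt(abs(ns$a2), 1)
  expect_gte(ns$loglik, st$loglik - 1e-8)
  expect_lt(ns$loglik - st$loglik, 2.5)
  expect_error(fit_gev_nonstationary(x, rep(1, 200)), "constant")
})

test_that("nonstationary parameters are recovered within replicate spread", {
  # tolerances frozen from a 100-replicate spread at these settings
  # (sd: a1 0.107, a2 0.085, sigma 0.033, xi 0.030); bands are +/- 5 sd
  set.seed(605)
  tt <- seq(0, 2, length.out = 500)
  x <- gev_rand(500, 5 + 3 * tt, 1, -0.1)
  fit <- fit_gev_nonstationary(x, tt)
  expect_lt(abs(fit$a1 - 5), 0.55)
  expect_lt(abs(fit$a2 - 3), 0.45)
  expect_lt(abs(fit$sigma - 1), 0.17)
  expect_lt(abs(fit$xi + 0.1), 0.15)
})

test_that("the likelihood-ratio test degenerates correctly and has power", {
  set.seed(606)
  tt <- seq(0.3, 1.2, length.out = 50)
  x <- gev_rand(50, 0, 1.5, -0.1)
  st <- fit_gev_stationary(x)
  ns <- fit_gev_nonstationary(x, tt)
  ns0 <- ns
  ns0$loglik <- st$loglik  # identical fits by construction
  lr0 <- llr_test(st, ns0)
  expect_equal(lr0$lambda_stat, 0)
  expect_equal(lr0$p_value, 1)
  expect_equal(lr0$selected, "stationary")
  # strong trend: rejection nearly always
  rej <- replicate(100, {
    y <- gev_rand(50, 3 * tt, 1, -0.1)
    llr_test(fit_gev_stationary(y),
             fit_gev_nonstationary(y, tt))$selected == "nonstationary"
  })
  expect_gt(mean(rej), 0.95)
  # mismatched data is an error
  other <- fit_gev_nonstationary(gev_rand(50, 0, 1.5, -0.1), tt)
  expect_error(llr_test(st, other), "identical data")
})

test_that("return periods follow the closed forms and censoring rules", {
  med <- gev_quantile(0.5, 2, 1, -0.1)
  m <- structure(list(kind = "nonstationary", a1 = 2, a2 = 0, sigma = 1,
                      xi = -0.1), class = "gev_model")
  expect_equal(return_period(m, 1, threshold = med)$return_period_years, 2,
               tolerance = 1e-10)
  gum <- structure(list(kind = "nonstationary", a1 = 0, a2 = 0, sigma = 1,
                        xi = 0), class = "gev_model")
  expect_equal(return_period(gum, 1, threshold = 0)$return_period_years,
               1 / (1 - exp(-1)), tolerance = 1e-10)
  # bounded tail with the threshold beyond the upper endpoint: censored
  bounded <- structure(list(kind = "nonstationary", a1 = -10, a2 = 0,
                            sigma = 1, xi = -0.2), class = "gev_model")
  rp <- return_period(bounded, 1, threshold = 0)
  expect_true(rp$censored)
  expect_equal(rp$return_period_years, 10000)
})

test_that("return periods match the exceedance frequency of simulation", {
  set.seed(607)
  m <- structure(list(kind = "nonstationary", a1 = -1, a2 = 1, sigma = 1.5,
                      xi = -0.1), class = "gev_model")
  for (lvl in c(1, 2)) {
    rp <- return_period(m, lvl)$return_period_years
    draws <- gev_rand(1e6, m$a1 + m$a2 * lvl, m$sigma, m$xi)
    p_hat <- mean(draws > 0)
    se <- sqrt(p_hat * (1 - p_hat) / 1e6)
    expect_lt(abs(1 / rp - p_hat), 4 * se)
  }
})

test_that("return periods decrease strictly with warming when a2 > 0", {
  m <- structure(list(kind = "nonstationary", a1 = -10, a2 = 3, sigma = 1.5,
                      xi = -0.1), class = "gev_model")
  rp <- return_period(m, seq(1, 3.5, by = 0.5))
  expect_true(all(diff(rp$return_period_years) < 0))
  expect_true(all(rp$return_period_years > 0))
})

test_that("stations are classified into frequency bands that sum to 100%", {
  tab <- data.frame(station_id = "S1", warming_level_c = 2,
                    return_period_years = 50, censored = FALSE)
  cls <- classify_return_periods(tab)
  expect_equal(cls$share_pct[cls$class == "10-100 yr"], 100)
  # ten stations with known return periods at one level
  rps <- c(2, 5, 8, 15, 40, 70, 120, 500, 10000, 10000)
  tab10 <- data.frame(station_id = sprintf("S%02d", 1:10),
                      warming_level_c = 2, return_period_years = rps,
                      censored = rps >= 10000)
  cls10 <- classify_return_periods(tab10)
  expect_equal(cls10$share_pct[cls10$class == "<10 yr"], 30)
  expect_equal(cls10$share_pct[cls10$class == "10-100 yr"], 30)
  expect_equal(cls10$share_pct[cls10$class == ">100 yr"], 40)
  expect_equal(sum(cls10$share_pct), 100)
  empty <- classify_return_periods(tab10[0, ])
  expect_equal(nrow(empty), 0)
})
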