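#' Generalized extreme value distribution functions
#'
#' CDF, quantile function and random generation for the three-parameter
#' GEV distribution with location `mu`, scale `sigma` and shape `xi`,
#' `F(x) = exp(-(1 + xi*(x - mu)/sigma)^(-1/xi))` on its support, with the
#' Gumbel limit `exp(-exp(-(x - mu)/sigma))` used when `|xi|` is below
#' `tol`. Shape convention: `xi > 0` heavy-tailed (Frechet), `xi < 0`
#' bounded right tail (Weibull), the typical regime for humid-heat
#' extremes.
#'
#' @param x quantile(s).
#' @param p probabilit(y/ies) in (0, 1).
#' @param n number of random draws.
#' @param mu location.
#' @param sigma scale, strictly positive.
#' @param xi shape.
#' @param tol threshold on `|xi|` below which the Gumbel limiting form is
#'   used (avoids overflow in `(.)^(-1/xi)`).
#' @return `gev_cdf` returns probabilities (0 below the lower endpoint,
#'   1 above a finite upper endpoint); `gev_quantile` quantiles; `gev_rand`
#'   random variates by inverse transform.
#' @export
gev_cdf <- function(x, mu, sigma, xi, tol = 1e-6) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  z <- (x - mu) / sigma
  if (abs(xi) < tol) {
    exp(-exp(-z))
  } else {
    t <- 1 + xi * z
    out <- numeric(length(z))
    inside <- t > 0
    out[inside] <- exp(-t[inside]^(-1 / xi))
    # outside the support: below lower endpoint (xi>0) -> 0;
    # above upper endpoint (xi<0) -> 1
    out[!inside] <- if (xi > 0) 0 else 1
    out
  }
}

#' @rdname gev_cdf
#' @export
gev_quantile <- function(p, mu, sigma, xi, tol = 1e-6) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  stopifnot(all(p > 0 & p < 1))
  if (abs(xi) < tol) {
    mu - sigma * log(-log(p))
  } else {
    mu + sigma * ((-log(p))^(-xi) - 1) / xi
  }
}

#' @rdname gev_cdf
#' @export
gev_rand <- function(n, mu, sigma, xi, tol = 1e-6) {
  gev_quantile(stats::runif(n), mu, sigma, xi, tol = tol)
}

# Negative log-likelihood of iid GEV observations, possibly with a
# per-observation location vector mu (for the nonstationary model).
gev_nll <- function(x, mu, sigma, xi, tol = 1e-6) {
  if (sigma <= 0) return(Inf)
  z <- (x - mu) / sigma
  n <- length(x)
  if (abs(xi) < tol) {
    n * log(sigma) + sum(z) + sum(exp(-z))
  } else {
    t <- 1 + xi * z
    if (any(t <= 0)) return(Inf)  # support condition
    n * log(sigma) + (1 + 1 / xi) * sum(log(t)) + sum(t^(-1 / xi))
  }
}

gev_optim <- function(par0, fn) {
  stats::optim(par0, fn, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 10000))
}

#' Fit a stationary GEV distribution by maximum likelihood
#'
#' Maximizes the GEV log-likelihood with the Nelder-Mead simplex, started
#' from Gumbel method-of-moments estimates
#' (`sigma0 = sd(x)*sqrt(6)/pi`, `mu0 = mean(x) - 0.5772*sigma0`) and a
#' small positive shape. The scale is optimized on the log scale to keep it
#' positive.
#'
#' @param maxima numeric vector of annual block maxima.
#' @param n_min minimum sample size accepted (default 20).
#' @param xi_init initial shape value.
#' @return Object of class `gev_model`: list with `kind = "stationary"`,
#'   `mu`, `sigma`, `xi`, `loglik`, `n`, `convergence` flag (0 = converged)
#'   and the fitted `data`.
#' @export
fit_gev_stationary <- function(maxima, n_min = 20, xi_init = 0.1) {
  x <- maxima[!is.na(maxima)]
  n <- length(x)
  if (n < n_min) {
    stop(sprintf("need at least %d block maxima, got %d", n_min, n))
  }
  s0 <- stats::sd(x) * sqrt(6) / pi
  if (!is.finite(s0) || s0 <= 0) stop("degenerate sample: zero variance")
  m0 <- mean(x) - 0.5772156649 * s0
  fn <- function(p) gev_nll(x, p[1], exp(p[2]), p[3])
  opt <- gev_optim(c(m0, log(s0), xi_init), fn)
  if (opt$convergence != 0) {
    warning("stationary GEV fit did not converge")
  }
  mod <- structure(
    list(kind = "stationary",
         mu = opt$par[1], sigma = exp(opt$par[2]), xi = opt$par[3],
         loglik = -opt$value, n = n, convergence = opt$convergence,
         data = x),
    class = "gev_model"
  )
  if (!is.finite(mod$loglik)) stop("stationary GEV fit failed (support violation)")
  mod
}

#' Fit a nonstationary GEV with location linear in a climate covariate
#'
#' The location is `mu_t = a1 + a2 * T_t`, where `T_t` is the GMST anomaly
#' for year t; scale and shape are constant. The fit is initialized from
#' the stationary solution with `a2 = 0`, so its log-likelihood can never
#' fall below the stationary one (the models are nested); if Nelder-Mead
#' drifts below, the stationary-equivalent parameters are returned.
#'
#' @param maxima annual block maxima.
#' @param covariate per-year GMST anomaly (degC above preindustrial), same
#'   length as `maxima`; must not be constant.
#' @param n_min minimum sample size accepted.
#' @return Object of class `gev_model` with `kind = "nonstationary"` and
#'   fields `a1`, `a2`, `sigma`, `xi`, `loglik`, `n`, `convergence`,
#'   `data`, `covariate`.
#' @export
fit_gev_nonstationary <- function(maxima, covariate, n_min = 20) {
  stopifnot(length(maxima) == length(covariate))
  ok <- !is.na(maxima) & !is.na(covariate)
  x <- maxima[ok]
  tt <- covariate[ok]
  if (length(unique(tt)) < 2) {
    stop("degenerate design: covariate is constant")
  }
  st <- fit_gev_stationary(x, n_min = n_min)
  fn <- function(p) gev_nll(x, p[1] + p[2] * tt, exp(p[3]), p[4])
  opt <- gev_optim(c(st$mu, 0, log(st$sigma), st$xi), fn)
  ll <- -opt$value
  par <- opt$par
  if (ll < st$loglik) {  # nesting guard: never below the stationary optimum
    par <- c(st$mu, 0, log(st$sigma), st$xi)
    ll <- st$loglik
  }
  structure(
    list(kind = "nonstationary",
         a1 = par[1], a2 = par[2], sigma = exp(par[3]), xi = par[4],
         loglik = ll, n = length(x), convergence = opt$convergence,
         data = x, covariate = tt),
    class = "gev_model"
  )
}

#' @export
print.gev_model <- function(x, ...) {
  if (x$kind == "stationary") {
    cat(sprintf("Stationary GEV: mu=%.4g sigma=%.4g xi=%.4g (loglik %.3f, n=%d)\n",
                x$mu, x$sigma, x$xi, x$loglik, x$n))
  } else {
    cat(sprintf(
      "Nonstationary GEV: mu(T)=%.4g + %.4g*T, sigma=%.4g xi=%.4g (loglik %.3f, n=%d)\n",
      x$a1, x$a2, x$sigma, x$xi, x$loglik, x$n))
  }
  invisible(x)
}

#' Kolmogorov-Smirnov goodness-of-fit test for a fitted GEV
#'
#' Plain KS test of the block maxima against the fitted stationary GEV CDF
#' at significance level `alpha`. Because the parameters are estimated from
#' the same data the plain test is conservative; it is used as-is, mirroring
#' standard practice in station screening.
#'
#' @param maxima block maxima used in the fit.
#' @param model stationary `gev_model`.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p_value`, `pass` (TRUE iff p >= alpha).
#' @export
ks_test <- function(maxima, model, alpha = 0.05) {
  stopifnot(inherits(model, "gev_model"), model$kind == "stationary")
  x <- maxima[!is.na(maxima)]
  kt <- suppressWarnings(stats::ks.test(
    x, function(q) gev_cdf(q, model$mu, model$sigma, model$xi)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       pass = kt$p.value >= alpha)
}

#' Likelihood-ratio test between nested stationary and nonstationary fits
#'
#' Computes `Lambda = 2 * (loglik_nonstationary - loglik_stationary)` and
#' compares it to a chi-squared distribution with 1 degree of freedom (the
#' models differ by the single location-slope parameter). The
#' nonstationary model is selected when p < alpha.
#'
#' @param stationary stationary `gev_model`.
#' @param nonstationary nonstationary `gev_model` fitted to the same data.
#' @param alpha significance level (default 0.05).
#' @return list of class `llr_result`: `lambda_stat`, `df`, `p_value`,
#'   `selected` ("stationary" or "nonstationary").
#' @export
llr_test <- function(stationary, nonstationary, alpha = 0.05) {
  stopifnot(inherits(stationary, "gev_model"),
            inherits(nonstationary, "gev_model"),
            stationary$kind == "stationary",
            nonstationary$kind == "nonstationary")
  if (stationary$n != nonstationary$n ||
      !isTRUE(all.equal(sort(stationary$data), sort(nonstationary$data)))) {
    stop("stationary and nonstationary fits must use identical data")
  }
  lambda <- max(0, 2 * (nonstationary$loglik - stationary$loglik))
  p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  structure(list(lambda_stat = lambda, df = 1L, p_value = p,
                 selected = if (p < alpha) "nonstationary" else "stationary"),
            class = "llr_result")
}

#' Return period of a noncompensable event at a warming level
#'
#' For a nonstationary GEV model the location at global warming level
#' `Delta T` is `a1 + a2 * Delta T`; the annual exceedance probability of
#' the threshold (0 = the compensability boundary) is
#' `p = 1 - F(threshold)`, and the return period is `1/p` years. Return
#' periods longer than `cap` (including an unreachable threshold when the
#' right tail is bounded, `xi < 0`) are right-censored at `cap`.
#'
#' @param model nonstationary `gev_model` (a stationary model is accepted;
#'   warming levels are then ignored and its fixed location used).
#' @param warming_level one or more GMST increases above preindustrial,
#'   degC (typical grid: 1.0 to 3.5 by 0.5).
#' @param threshold event threshold on the exceedance-scalar block maximum
#'   (default 0, i.e. any 6-h-mean noncompensable state).
#' @param cap censoring cap in years (default 10000).
#' @return data.frame with `warming_level_c`, `return_period_years`
#'   (censored entries carry the cap value) and logical `censored`.
#' @export
return_period <- function(model, warming_level, threshold = 0, cap = 10000) {
  stopifnot(inherits(model, "gev_model"))
  mu <- if (model$kind == "nonstationary") {
    model$a1 + model$a2 * warming_level
  } else {
    rep(model$mu, length(warming_level))
  }
  p <- 1 - vapply(mu, function(m)
    gev_cdf(threshold, m, model$sigma, model$xi), numeric(1))
  censored <- p < 1 / cap
  rp <- ifelse(censored, cap, 1 / p)
  data.frame(warming_level_c = warming_level,
             return_period_years = rp,
             censored = censored)
}

#' Return periods for many stations at a grid of warming levels
#'
#' @param fits named list of nonstationary `gev_model` objects, one per
#'   station (names = station ids).
#' @param levels warming-level grid, degC (default 1.0-3.5 by 0.5).
#' @param threshold,cap passed to [return_period()].
#' @return Long data.frame: `station_id`, `warming_level_c`,
#'   `return_period_years`, `censored`.
#' @export
return_period_table <- function(fits, levels = seq(1, 3.5, by = 0.5),
                                threshold = 0, cap = 10000) {
  out <- lapply(names(fits), function(id) {
    rp <- return_period(fits[[id]], levels, threshold = threshold, cap = cap)
    cbind(station_id = id, rp)
  })
  do.call(rbind, out)
}

#' Classify stations by return-period frequency bands
#'
#' Bins each station's return period at each warming level into frequency
#' classes — by default: more frequent than 1-in-10 years, between 1-in-10
#' and 1-in-100, and less frequent than 1-in-100 — and reports the share of
#' stations per class. Censored return periods fall in the rarest class.
#' Shares are computed relative to the stations present in the table (the
#' subset retained by the GEV screening).
#'
#' @param table output of [return_period_table()].
#' @param breaks ascending break points in years (default `c(10, 100)`).
#' @return data.frame with `warming_level_c`, `class` (factor), `share_pct`.
#' @export
classify_return_periods <- function(table, breaks = c(10, 100)) {
  if (nrow(table) == 0) {
    return(data.frame(warming_level_c = numeric(0), class = character(0),
                      share_pct = numeric(0)))
  }
  stopifnot(!is.unsorted(breaks))
  lab <- c(sprintf("<%g yr", breaks[1]),
           if (length(breaks) > 1)
             sprintf("%g-%g yr", breaks[-length(breaks)], breaks[-1]),
           sprintf(">%g yr", breaks[length(breaks)]))
  cls <- cut(table$return_period_years, c(-Inf, breaks, Inf), labels = lab)
  tab <- table(warming_level_c = table$warming_level_c, class = cls)
  share <- 100 * prop.table(tab, margin = 1)
  out <- as.data.frame(share, responseName = "share_pct")
  out$warming_level_c <- as.numeric(as.character(out$warming_level_c))
  out[order(out$warming_level_c, out$class), c("warming_level_c", "class",
                                               "share_pct")]
}
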