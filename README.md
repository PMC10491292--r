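# noncompheat

Statistical detection and projection of **noncompensable heat stress** —
environmental conditions under which a healthy human can no longer hold a
stable core temperature without external cooling. Because core
temperature rises at about 1 °C/hour under such conditions, six hours of
exposure can carry a normal 37 °C core to the 43 °C lethal limit; the
package therefore analyzes 6-hour exposure windows by default (9 and 12
hours as sensitivity settings).

The package is written for climate and health-impact researchers who
work with daily weather-station statistics and climate-model output. It
implements, end to end:

* **Compensability threshold** — a quadratic `q(T) = c₂T² + c₁T + c₀`
  fitted to calibration points in dry-bulb temperature / relative
  humidity space. A state's severity is its signed exceedance scalar
  `s = RH − q(T)` (positive = noncompensable); `binarize()` maps it to a
  0/1 flag.
* **Diurnal reconstruction** — hourly series from daily max/min/mean via
  fixed 24-h sinusoids in 180° antiphase (only the amplitude is taken
  from the data), then annual block maxima of the 6-hour-mean exceedance.
* **Station quality control** — staged filters (land, |lat| ≤ 60°, ≤ 50%
  missing, no early-record maximum, inhomogeneity ≤ 1 °C) and two-tier
  gap filling: within-station harmonic regression for runs < 5 days,
  nearest-3-neighbor regression within 100 km for longer runs.
* **Extreme value inference** — stationary and nonstationary GEV fits to
  the annual maxima x_t,

  F(x; μ, σ, ξ) = exp{ −[1 + ξ(x−μ)/σ]^(−1/ξ) },  μ_t = a₁ + a₂·T_t,

  where T_t is the global-mean surface temperature (GMST) anomaly;
  Kolmogorov-Smirnov screening, χ²(1) likelihood-ratio model selection,
  and return periods 1/(1 − F(0)) at warming levels 1.0–3.5 °C.
* **Ensemble pooling** — per-member 30-year warming windows (earliest
  window whose mean GMST reaches the level) and pooled empirical return
  periods N/k over, e.g., 17 × 30 = 510 member-years.
* **Synthetic data** — station networks and ensembles with known
  ground-truth GEV structure (annual maxima exactly GEV with location
  a₁ + a₂·GMST by max-stability), so every stage has a recoverable
  target.

## Worked example

```r
library(noncompheat)

cfg <- synthetic_config(seed = 2)        # 6 stations, 1971-2020
net <- generate_station_network(cfg)
thr <- fit_threshold(generate_calibration_points(noise_sd = 0))
thr
#> Compensability threshold: q(T) = -0.1*T^2 + 4*T + 51.6
#>   R^2 = 1, fit domain [36, 46] degC

res <- analyze_station_network(net$daily, net$meta, net$gmst, thr,
                               period = c(1971, 2020))
res$fits[, c("station_id", "a2", "sigma", "xi", "ks_p", "llr_p", "selected")]
#>        station_id   a2 sigma      xi  ks_p    llr_p      selected
#> SYN001     SYN001 3.06  1.50 -0.2596 0.889 7.28e-04 nonstationary
#> SYN002     SYN002 2.34  1.46 -0.3423 0.750 3.64e-03 nonstationary
#> SYN003     SYN003 4.12  1.54 -0.1256 0.899 3.81e-05 nonstationary
#> SYN004     SYN004 3.05  1.29 -0.0782 1.000 4.41e-04 nonstationary
#> SYN005     SYN005 4.42  1.45 -0.0420 0.974 5.96e-06 nonstationary
#> SYN006     SYN006 4.19  1.35 -0.1720 0.917 2.43e-06 nonstationary

subset(res$return_periods, station_id == "SYN001")
#>   station_id warming_level_c return_period_years censored
#> 1     SYN001             1.0           10000.000     TRUE
#> 2     SYN001             1.5            3776.340    FALSE
#> 3     SYN001             2.0              40.785    FALSE
#> 4     SYN001             2.5               5.823    FALSE
#> 5     SYN001             3.0               1.974    FALSE
#> 6     SYN001             3.5               1.179    FALSE
```

Reading the output: the network was generated with a true warming
response of a₂ = 3 humidity points per °C of global warming; the six
recovered slopes scatter around it, every station passes the KS screen
(`ks_p ≥ 0.05`), and the likelihood-ratio test selects the nonstationary
model throughout (`llr_p < 0.05`). For station SYN001 a noncompensable
6-hour event is rarer than the 10,000-year censoring cap at 1 °C of
warming but approaches an annual event by 3.5 °C — the steep-right-tail
behavior (ξ < 0) that makes humid-heat return periods collapse under
small location shifts.

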