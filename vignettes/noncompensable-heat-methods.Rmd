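---
title: "Detecting and projecting noncompensable heat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and projecting noncompensable heat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncompheat)
```

## The scientific problem

Noncompensable heat stress is the set of environmental conditions under
which a healthy human can no longer hold a stable core temperature
without external cooling. Because core temperature rises at roughly
1 °C/hour under such conditions, six hours of exposure can carry a
normal 37 °C core to the 43 °C lethal limit — hence the package's default
6-hour exposure window (`lethal_exposure_hours()`), with 9- and 12-hour
sensitivity settings.

`noncompheat` implements an end-to-end statistical pipeline for asking
where and how often such conditions occur as the planet warms:

1. an empirical **compensability threshold** in dry-bulb temperature /
   relative humidity space,
2. **diurnal reconstruction** of hourly series from daily station
   statistics,
3. staged **station quality control** with two-tier gap filling,
4. **nonstationary generalized extreme value (GEV)** inference on annual
   windowed block maxima, with return periods at prescribed
   global-warming levels, and
5. **ensemble pooling** of climate-model members sampled at warming
   levels.

A sixth module generates synthetic station networks and ensembles with
known ground truth, so every stage has a recoverable target.

## The compensability threshold

Laboratory compensability limits are summarized by a quadratic
`q(T) = c2·T² + c1·T + c0` giving the critical relative humidity at
dry-bulb temperature `T`; states above the curve are noncompensable.
`fit_threshold()` estimates the coefficients by ordinary least squares on
the humidity axis (`r_squared = 1 − SS_res/SS_tot`), requiring at least
three distinct temperatures.

The severity of a state is its **exceedance scalar**
`s = RH − q(T)` (humidity percentage points): zero on the curve,
negative compensable, positive noncompensable. We use the vertical
signed offset rather than the perpendicular distance because it keeps
the quoted sign/zero semantics, is strictly monotone in severity at
fixed temperature, and every downstream quantity that matters (the
binary flag, exceedance of the 0 threshold by block maxima) is invariant
to the choice of any strictly monotone, zero-preserving rescaling.
`binarize()` classifies the boundary `s = 0` as compensable (only
strictly positive scalars are noncompensable).

Two cautions, both consequences of the method rather than the code:

* The quadratic is calibrated over a narrow hot range (the synthetic
  calibration set spans 36–46 °C). Evaluating `q` far below the
  `fit_domain` is extrapolation; with noisy calibration points the
  extrapolated curve can wander by tens of humidity points at 20–30 °C.
  Block maxima are driven by the hottest hours, which lie near the
  domain, but users supplying their own calibration data should check
  `fit_domain` against their climate.
* Calibration points are an input (CSV with `temperature_c`,
  `humidity_pct`, `label`), not constants: the averaged laboratory
  values are not published in numeric form, so the package ships a
  generator of clearly labelled synthetic stand-ins
  (`generate_calibration_points()`).

`wet_bulb()` (iterative psychrometric solution at a default 1013.25 hPa)
is provided as a diagnostic for comparing states against wet-bulb
isopleths such as the proposed 35 °C survivability limit; it feeds no
pipeline stage.

## Diurnal reconstruction

Sub-daily records are often unavailable or irregular, so hourly series
are reconstructed from daily statistics. Temperature and relative
humidity are treated as 24-hour sinusoids in antiphase: only the
amplitude is taken from the data (`A = (max − min)/2`, offset = mean),
the frequency is fixed at 24 h and the relative phase at 180°. A pure
sinusoid cannot honor max, min *and* a mean different from
`(max+min)/2`; we honor mean and amplitude, which preserves the daily
mean exactly (a cosine sampled at 24 equispaced points sums to zero).

The absolute clock phase is not identified by the daily statistics; the
temperature peak is fixed at 15:00 local (climatologically typical), the
humidity peak therefore at 03:00. The absolute phase shifts which clock
hours a window covers but not the windowed maxima on stationary days.

From the hourly exceedance series, `windowed_block_maximum()` takes the
largest mean over any `window_hours` contiguous hours (windows roll
across day boundaries; a window is attributed to the year of its first
hour), and `annual_block_maxima()` pairs each year's maximum with that
year's global-mean surface temperature (GMST) anomaly.
`count_noncompensable_events()` counts maximal non-overlapping windows
of consecutive noncompensable hours, tiled greedily left to right (13
consecutive hot hours = two 6-hour events); whether observed event
counts should use overlapping windows is not settled, and the greedy
rule is the conservative choice.

## Station quality control

`filter_stations()` applies, in order: remove non-land stations; remove
stations poleward of 60°; remove stations missing more than 50% of
their daily records in the analysis period (1970–2020 by default; the
unit of missingness is the day with all six statistics present); remove
stations whose highest windowed-mean exceedance in 1950–1990 beats the
highest after 2000 (a screen against spurious early extremes, computed
with the same diurnal/windowing machinery as the main analysis); and
remove stations whose temperature inhomogeneity metadata is missing or
exceeds 1 °C. Inhomogeneity values are consumed as metadata from an
upstream pairwise homogenization; computing them is out of scope. Each
removal is attributed to the first failing filter, and the audit
(`qc_report`) satisfies removals + kept = input.

The early-maximum screen deserves a note: comparing two era maxima is
intrinsically noisy. Under a realistic warming signal (location trend of
a few humidity points over the record against an interannual scale of
1–2 points), around a fifth of genuinely trending stations fail it by
chance. That is a property of the filter, not a bug; it is why the
synthetic defaults use a cluster of six partially decorrelated stations
rather than one.

Gap filling is two-tier, mirroring standard practice:

* **Short runs** (fewer than five consecutive missing days,
  `fill_short_gaps()`): each field is regressed on a linear trend plus
  annual and semiannual harmonics fitted to the station's own
  non-missing days — the standard climatological choice for an
  under-specified "nonlinear regression of the remaining series". The
  method is pluggable in the sense that the design matrix is isolated in
  one place.
* **Long runs** (five days or more, `fill_long_gaps()`): the three
  geographically closest stations with *complete* records within 100 km
  (haversine distance) serve as predictors in a per-field multivariate
  linear regression fitted on the target's non-missing days. Fewer than
  three such neighbors is a *rejection* of the station (a normal QC
  outcome carried in the report), not an error.

Gap filling never alters non-missing values. `check_autocorrelation()`
reports the lag-1 coefficient of the annual maxima and flags
`|r1| > 2/√n`; the flag is informational — block maxima are examined for
serial dependence but not corrected, matching the source procedure.

## Extreme value inference

Annual block maxima `x_t` are modeled by the GEV distribution

$$F(x;\mu,\sigma,\xi) = \exp\left\{-\left[1 + \xi\left(\tfrac{x-\mu}{\sigma}\right)\right]^{-1/\xi}\right\}$$

with the Gumbel form `exp(−exp(−(x−μ)/σ))` used when `|ξ| < 10⁻⁶` to
avoid overflow. ξ > 0 is the heavy-tailed Fréchet regime; ξ < 0 the
bounded Weibull regime typical of humid-heat extremes (a convective
ceiling caps how much moisture the boundary layer can hold, so small
location shifts produce large return-period changes).

* `fit_gev_stationary()`: maximum likelihood by Nelder-Mead (function
  tolerance 10⁻⁸, up to 10⁴ evaluations) from Gumbel method-of-moments
  starts (`σ₀ = sd·√6/π`, `μ₀ = mean − 0.5772·σ₀`), with the scale
  optimized on the log scale. At least 20 maxima are required by
  default.
* `ks_test()`: plain Kolmogorov-Smirnov screen of the maxima against
  the fitted CDF at `α = 0.05`. With estimated parameters the plain
  test is conservative (it passes distribution-true samples essentially
  always); it is used unmodified because that is how station screening
  is done in practice, and the conservatism only lets marginal stations
  through to the likelihood-ratio stage.
* `fit_gev_nonstationary()`: location linear in the GMST anomaly,
  `μ_t = a1 + a2·T_t`, scale and shape constant (only the location
  carries the covariate; the shape is a single constant-in-time
  parameter in both models, free across stations). Initialized from the
  stationary solution with `a2 = 0`, so the nonstationary log-likelihood
  can never fall below the stationary one; a guard returns the
  stationary-equivalent parameters if the simplex drifts.
* `llr_test()`: `Λ = 2(ℓ_ns − ℓ_st)` against χ²(1); the nonstationary
  model is selected when `p < 0.05`. At the 50-year sample sizes of a
  1970–2020 record the χ² approximation is known to be slightly
  liberal: in our null simulations the empirical type-I error is about
  0.06 at n = 50, falling to ≈0.055 at n = 200. We implement the plain
  test (no Bartlett correction), as the screening procedure prescribes,
  and surface the consequence here: expect roughly 5–6% of truly
  trendless stations to be retained spuriously, with no multiple-testing
  adjustment applied.

`return_period()` evaluates the annual exceedance probability
`p = 1 − F(0; a1 + a2·ΔT, σ, ξ)` at warming level ΔT (default grid 1.0
to 3.5 °C by 0.5) and reports `1/p` years, right-censored at 10⁴ years
(including the case of a bounded tail whose endpoint lies below the
threshold). `classify_return_periods()` bins stations into
more-frequent-than-decadal, decadal-to-centennial, and
rarer-than-centennial classes, with shares computed over the stations
retained by the GEV screens.

`analyze_station_network()` chains all of the above.

## Ensemble pooling

Climate-model members differ in climate sensitivity, so projections are
sampled at **warming levels**, not calendar periods:
`select_warming_window()` finds the earliest 30-year span whose mean
GMST anomaly first reaches the level (an explicit not-reached signal
otherwise). Within the windows, each member contributes 30 years of
annual block maxima, and `pooled_return_period()` estimates the return
period empirically as `N/k` (pool years over exceedance years),
censored as "> N years" when no exceedance occurs — with 17 members the
pool is 510 member-years per level, roughly ten times a single
station's 50-year record. The plain `N/k` estimator (not
`(N+1)/(k+1)`) is used because the pooled years are treated as direct
observations of the climate state; censoring, not smoothing, handles
`k = 0`.

## The synthetic world

`generate_station_network()` builds inputs whose answers are known:

* **GMST**: linear trend plus white noise (defaults 0.018 °C/yr, sd
  0.05 °C, 0.3 °C above preindustrial in 1971 — the observed magnitude
  of late-20th-century warming).
* **Block-maxima structure**: for each extreme-season day (days of year
  152–241), a target peak 6-hour-mean exceedance is drawn iid from a
  per-day GEV chosen by inverting max-stability, so the *annual maximum
  over the season is exactly* GEV(a1 + a2·GMST_t, σ, ξ). Defaults
  a1 = −10, a2 = 3 (humidity points per °C of global warming),
  σ = 1.5, ξ = −0.1 describe a hot station a few points below the
  boundary today that crosses it near 3.3 °C of warming — the regime of
  interest. Off-season days follow a seasonal envelope far below the
  summer values.
* **Inversion through the real machinery**: the generator does not
  write block maxima directly. It solves, per day, for the daily mean
  humidity such that the reconstructed hourly series (the actual
  `reconstruct_hourly()` map, antiphase humidity and all) attains the
  target windowed exceedance. The diurnal and windowing stages are
  therefore genuinely exercised, and the induced annual maxima are
  GEV up to two small approximations: windows that straddle midnight
  (the within-day afternoon window dominates in practice) and humidity
  clipping at the physical bounds (kept inactive by the default
  climatology).
* **Space**: stations are scattered within 40 km of a cluster center
  and share a common daily signal through a Gaussian copula with
  loading `exp(−d/60 km)` — strong enough for neighbor regression to be
  learnable, weak enough that the early-maximum filter does not remove
  whole clusters at once. Co-located stations are perfect copies.
* **Defects**: short (1–4 day) and long (5–15 day) missing runs start
  with per-day probabilities 0.002 and 2×10⁻⁵; inhomogeneities are
  injected as mid-record temperature steps with the step size recorded
  in the metadata, emulating an upstream homogenization audit.

`generate_ensemble()` reuses the same day-level machinery per member
with member-specific warming rates (multiples 1.0–1.4 of a
0.025 °C/yr reference ramp over 1950–2100), so all members share one
climate-state distribution conditional on GMST.

What the synthetic world does *not* emulate: weather autocorrelation
(days are exchangeable within a season), fronts/monsoons/ENSO,
station-specific climatologies within a cluster, observation-time
biases, or humidity inhomogeneities. Passing tests therefore
demonstrate that the statistical machinery recovers known structure
through the full chain — not that real station archives satisfy the
model's assumptions.

## Numerical choices and problem sizes

* Nelder-Mead: function tolerance 10⁻⁸, max 10⁴ evaluations; log-scale
  optimization keeps σ > 0; the support condition
  `1 + ξ(x−μ_t)/σ > 0` is enforced by an infinite penalty.
* Gumbel switch at `|ξ| < 10⁻⁶`; continuity at the switch is tested to
  10⁻⁶.
* Ties/boundaries: exceedance 0 is compensable; censoring cap 10⁴
  years; degenerate designs (constant covariate, < 3 distinct
  calibration temperatures, constant maxima) raise errors rather than
  producing numbers.
* Validation experiments run at deliberately modest sizes chosen to
  exercise every stage while keeping the suite quick: 100 full-pipeline
  replicates of a 6-station, 50-year network; 2000 null simulations of
  50-year records for the likelihood-ratio calibration; 10⁶ draws for
  the return-period sampling oracle; tolerance bands frozen from
  replicate spreads measured once (±4–5 sd).

## Known limitations

* The quadratic threshold extrapolates poorly outside its calibration
  domain (see above); a single threshold also ignores acclimatization,
  wind, radiative load and age structure.
* The sinusoidal day has one harmonic; skewed diurnal cycles and
  sub-hourly structure are out of scope.
* The χ²(1) likelihood-ratio screen is finitely liberal at 50-year
  records (~6% type-I rather than 5%), and no multiple-testing
  correction is applied across stations.
* Return periods are point estimates; confidence intervals are not
  produced.
* Bias correction/downscaling of model output and the computation of
  homogenization statistics are consumed as upstream inputs, never
  performed.
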