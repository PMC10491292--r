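Package: noncompheat
Title: Noncompensable Heat Stress Detection and Nonstationary Extreme
    Value Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and projecting noncompensable heat stress,
    the environmental conditions under which a healthy human can no longer
    maintain a stable core temperature without external cooling. Fits an
    empirical compensability threshold in temperature-humidity space,
    reconstructs hourly series from daily station statistics by fixed-phase
    sinusoids, applies staged weather-station quality control with two-tier
    gap filling, fits stationary and nonstationary generalized extreme value
    (GEV) models to annual windowed block maxima with a global-mean surface
    temperature covariate, and computes return periods at prescribed global
    warming levels from both station records and pooled climate-model
    ensembles. Includes a synthetic station and ensemble generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
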