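Package: pmgamm
Title: Two-Stage Penalized-Spline GAMMs for Spatio-Temporal Particulate
    Matter Exposure Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits two-stage generalized additive mixed models of monthly
    fine (PM2.5), inhalable (PM10), and coarse-mode (PM2.5-10) particle
    mass over large planar domains from geographic and meteorological
    covariates.  Stage one back-fits, separately by region, site
    intercepts, monthly intercepts, one-dimensional penalized-spline
    covariate effects, and monthly (or seasonal) thin-plate spatial
    surfaces; stage two smooths the estimated site intercepts over the
    whole domain with land-use covariate smooths and a domain-wide
    spatial term.  Includes a ratio-based historical PM2.5
    reconstruction from predicted PM10, native-scale delta-method error
    propagation with prediction intervals, site-exclusive 10-fold
    cross-validation with bias and precision metrics (CV R2, spatial CV
    R2, NMBF, NMEF, CVMAE, major-axis slope, interval coverage), a
    forward/backward covariate-selection procedure, and a synthetic-data
    generator emulating multi-network monitoring panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
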