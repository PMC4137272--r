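---
title: "Two-stage penalized-spline GAMMs for monthly particulate matter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage penalized-spline GAMMs for monthly particulate matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pmgamm` estimates monthly outdoor concentrations of fine (PM\\(_{2.5}\\)),
inhalable (PM\\(_{10}\\)) and coarse-mode (PM\\(_{2.5-10}\\)) particle mass at
arbitrary locations of a large planar domain, from monitoring panels plus
geographic and meteorological covariates.  The generative model for the
natural-log monthly concentration at site \\(i\\), month \\(t\\), region
\\(r\\) is the additive mixed model

\\[
y_{i,t} = \alpha + \alpha_{t,r} + \sum_q d_q(X_{i,q}) +
\sum_p f_{p,r}(Z_{i,t,p}) + g_{t,r}(s_i) + g(s_i) + b_i + e_{i,t},
\\]

with \\(b_i \sim N(0, \sigma^2_b)\\) a site random effect and
\\(e_{i,t} \sim N(0, \sigma^2_{e\,r,t})\\) heteroscedastic by region and
month.  \\(X\\) are time-invariant geographic covariates (elevation, urban
land use, population and emission densities, truncated road distance),
\\(Z\\) are monthly covariates (smoothed wind speed, temperature,
precipitation, air stagnation), \\(d_q\\) and \\(f_{p,r}\\) are
one-dimensional penalized spline smooths (basis dimension 10), and
\\(g_{t,r}\\), \\(g\\) are bivariate thin-plate regression splines for
residual monthly regional and long-term domain-wide spatial variability.

Fitting is in two stages.  **Stage 1** works region by region (with all
out-of-region sites within 400 km included as a buffer against boundary
effects) and back-fits two blocks until the fitted values stabilize: the
joint block — site intercepts \\(u_i\\), mean-zero monthly intercepts
\\(\alpha_{t,r}\\), and the \\(f_{p,r}\\) smooths — and the per-month
spatial surfaces \\(g_{t,r}\\), each fit to the other block's partial
residuals.  Buffer-site intercepts are discarded afterwards.  **Stage 2**
pools the in-region \\(\hat u_i\\) (the covariate-adjusted long-term site
means) across the whole domain and fits
\\(\hat u_i = \alpha + \sum_q d_q(X_{i,q}) + g(s_i) + b_i\\), with the
residual variance estimating \\(\sigma^2_b\\).

The historical PM\\(_{2.5}\\) reconstruction replaces the response by the
log ratio of observed PM\\(_{2.5}\\) to *predicted* PM\\(_{10}\\), after
deleting records whose PM\\(_{2.5}\\) exceeds 1.5 times predicted
PM\\(_{10}\\) (strict inequality).  This variant drops the monthly
intercepts in favor of a temporal smooth \\(h(t)\\) of the month index
(they would be exactly collinear), uses seasonal rather than monthly
regional surfaces (winter = Dec–Feb, spring = Mar–May, summer = Jun–Aug,
autumn = Sep–Nov), and carries predicted PM\\(_{10}\\) as an extra
time-varying covariate.  Predicted ratios are truncated at one, multiplied
by predicted PM\\(_{10}\\) to give PM\\(_{2.5}\\), and coarse mass is the
difference of the PM\\(_{10}\\) and PM\\(_{2.5}\\) predictions.

## The penalized-spline engine

Every term above is fit by one routine, `fit_penalized()`, which solves
penalized least squares over a parametric block plus smooth blocks and
selects each smoothing parameter by generalized cross-validation,
\\(GCV(\lambda) = n\,RSS/(n - \gamma\,edf)^2\\).  The multiplier
\\(\gamma\\) inflates the price of effective degrees of freedom; 1.4 is
used for all covariate and spatial smooths, and 1.8 for regions designated
data-sparse.  Design choices that the model family leaves open were fixed
as follows:

* **1-D basis**: cubic B-splines with knots at quantiles of the distinct
  covariate values.  The penalty is a second-order *divided-difference*
  penalty on the Greville abscissae, so its null space is exactly the
  constant and linear functions for any knot layout; at
  \\(\lambda \to \infty\\) a smooth collapses to the least-squares line.
* **Spatial basis**: eigen-truncated thin-plate splines — the radial
  kernel \\(r^2 \log r\\) on the distinct construction points, truncated
  to the leading eigen-directions, with the 3-dimensional polynomial null
  space (constant + two linear coordinates) separated out so the penalty
  annihilates it exactly.  Construction coordinates are standardized to a
  unit box; at most 600 construction points are used, thinned by a
  deterministic farthest-point rule.  Spatial basis dimensions follow the
  data: \\(k_{t,r} = \lfloor 0.9\,I_{t,r}\rfloor\\) per month-region and
  \\(k = \lfloor 0.9\,(I-Q)\rfloor\\) for the stage-2 surface, reduced
  when the total column count would approach the number of sites.
* **Smoothing-parameter search**: a 41-point log-spaced grid on
  \\([10^{-6}, 10^6]\\) per term with golden-section refinement,
  coordinate-wise cycling (2 sweeps) for multi-term fits.  Penalties are
  internally rescaled — normalized, then balanced against each term's
  design block — so this grid always spans interpolation to the
  null-space limit; fixed smoothing parameters supplied by the user are
  interpreted on this internal scale.  Ties (a perfect fit at every
  \\(\lambda\\)) resolve to the smoothest candidate.
* **Identifiability**: each smooth absorbs a sum-to-zero constraint over
  its training points; constants live in the parametric block.  Site
  intercepts carry the level, monthly intercepts are mean-zero within
  region, and each monthly surface is centered over its month's sites.
* **Inference**: the Bayesian posterior covariance
  \\(\hat\sigma^2 (X'WX + \sum_j \lambda_j S_j)^{-1}\\) feeds prediction
  variances and Wald tests of smooth terms (pseudo-inverse quadratic form,
  \\(\chi^2\\) with the rounded term edf as degrees of freedom).  Each
  1-D smooth is limited to at most 6 edf by raising its smoothing
  parameter (monotone bisection, tolerance 0.05).

## Back-fitting convergence

Plain alternation between the joint block and the monthly surfaces
converges slowly here, because site indicators and near-saturated monthly
surfaces span strongly overlapping spaces.  The package exploits that once
the smoothing parameters are frozen (they are re-selected by GCV in the
first 3 sweeps, then fixed), one sweep is an affine map of the current
spatial contribution, so the fixed point solves a linear system.  That
system is solved by GMRES using cached Cholesky factors of the two blocks'
normal equations, warm-started at the current iterate, and the solution is
then verified by plain sweeps against the convergence tolerance (default
\\(10^{-4}\\) on the log scale, maximum 20 sweeps).  This reproduces the
direct joint penalized least-squares solution to near machine precision
while keeping the per-sweep cost of ordinary back-fitting.

## Prediction and uncertainty

Predictions at new site-months compose the stage-2 component (intercept,
\\(d_q\\) smooths, domain surface) and the stage-1 component of the site's
region (monthly intercept, \\(f_{p,r}\\) smooths, monthly or seasonal
surface, \\(h(t)\\) when present).  Covariates at prediction locations are
first clamped to their training ranges — globally for time-invariant
covariates, within the site's region for time-varying ones — and
transformed with the *training* shift constants (`ln(z - min z + 10)` for
right-skewed densities, `sqrt(z - min z + 1)` for elevation; the training
minimum is never recomputed).

The prediction variance adds, as independent pieces, the stage-2 posterior
variance at the location, the surface posterior variance, and the
monthly-intercept variance; observation-level intervals further add
\\(\hat\sigma^2_b\\) and the region-month residual variance
\\(\hat\sigma^2_{e\,r,t}\\) (estimated from stage-1 residuals with an
edf-proportional denominator correction).  Direct variants exponentiate
log-scale normal intervals; native-scale standard errors use the
first-order delta method (\\(se = e^{\mu}\sigma_{\log}\\), within 10% of
Monte-Carlo truth for \\(\sigma_{\log} \le 0.3\\)).  The ratio chain
propagates variance through the product
(\\(var = r^2 var_{10} + PM_{10}^2 var_r\\), independence) and the coarse
fraction through the difference (\\(se = \sqrt{se_{10}^2 + se_{25}^2}\\)),
with native normal intervals floored at zero; non-positive coarse
predictions are flagged and excluded from validation metrics but retained
in output.

## Validation design and metrics

Cross-validation is site-exclusive: whole sites are randomly assigned to
10 sets; set 10 is reserved during covariate selection so
selection-induced over-fitting can be detected, and sets 1–9 are left out
in turn with the full pipeline refit each time.  For the historical ratio
model, validation is confined to one well-monitored evaluation year: sites
qualify with at least 10 monthly values in that year and at least 70
overall, a random subset of qualifying sites is withheld from CV to keep
the year's site density comparable to sparse years (25 candidate
withholdings are drawn and the one with the best spatial spread — largest
minimum nearest-neighbor distance — is kept), and the rest are folded.

Metrics, all on the native scale: CV \\(R^2\\) (squared Pearson
correlation of left-out observations and predictions), spatial CV
\\(R^2\\) (same after collapsing to one long-term mean per site), the
normalized mean bias and error factors (symmetric: over-prediction by a
factor of two gives NMBF = +100%, under-prediction −100%; NMEF ≥ |NMBF|
always), CVMAE, the major-axis slope of log observations on log
predictions (first principal axis of the centered cloud), and 95%
prediction-interval coverage.  The NMBF/NMEF algebra follows the
normalized mean bias/error factor definitions of S. Yu and colleagues;
reports can be stratified by region, season and urban tertile, with
flagged coarse records counted as excluded.

Covariate selection proceeds in the order: drop each time-varying term
that does not improve monthly CV \\(R^2\\); greedily add time-invariant
candidates by spatial CV \\(R^2\\) (minimum improvement 0.002,
configurable — the model family provides no threshold); drop terms with
Wald p > 0.05; and drop candidates whose fitted net trend (difference of
means over the top and bottom covariate quintiles) contradicts the
a-priori expected physical direction.  Because stage 1 does not depend on
which time-invariant covariates enter stage 2, the candidate search only
refits the cheap second stage on fixed fold-wise site intercepts.

## The synthetic study conditions

The generator emulates the structure of multi-network monitoring panels:
150 sites in 3 contiguous regions over 24 months in the default scenario
(600/7/60 in the large one), a clustered point process so urban tertiles
are meaningful, right-skewed density covariates (more than 10% of road
distances exceed the 500 m truncation point), seasonal meteorology with
spatial correlation, and log-normal PM driven by closed-form covariate
effects, Gaussian-bump spatial fields, site effects and region-month
heteroscedastic noise, with 10% completely-at-random missingness.  Three
realism choices matter for interpretation:

* spatial fields are **continuous across region boundaries** — the
  regional surfaces and 400 km buffers in the model are an estimation
  device, not a property of the atmosphere;
* monthly anomaly fields are **synoptic-scale broad** (bump scales
  500–1200 km) while the long-term field is sharper, mirroring the
  observation that fitted monthly surfaces need far fewer degrees of
  freedom than the long-term surface;
* elevation carries **substantial local relief** (180 m site-level SD) on
  top of broad orography, so it is not a deterministic function of the
  coordinates and its effect is identifiable next to the spatial term.

The noise scale is calibrated by root-finding so the predictable structure
explains a configured fraction (default 0.8) of the native-scale variance;
the realized fraction is returned with the truth object.  At the default
scenario size, pooled 10-fold monthly CV \\(R^2\\) lands near 0.73–0.75:
the gap to 0.8 is the estimation ceiling of re-fitting a fresh spatial
surface every month from ~50 regional sites, and varies by roughly ±0.03
across generator seeds.  Passing tests on these panels demonstrate correct
mechanics and calibrated uncertainty under the assumed structure; they do
not certify performance on real networks, whose missingness is informative,
whose fields are non-stationary, and whose covariates are measured with
error.

## Numerical notes and limitations

* Test-suite and acceptance computations use the scenario sizes stated
  above; the large scenario exists for scaling checks.
* The Wald reference distribution uses rounded edf — adequate for
  screening (empirical size ≈ 0.05–0.08 at nominal 0.05), not exact.
* GCV ties and rank-deficient designs are handled by preferring smoother
  fits and dropping dependent columns with a warning.
* Months with fewer than 5 sites contribute a zero spatial surface;
  regions with fewer than 15 sites are pooled with the reference group in
  interaction tests.
* Extrapolation far outside a surface's training hull inherits the
  thin-plate kernel's growth; covariate clamping limits but does not
  remove this.
* Full-fidelity model serialization uses RDS; the delimited-text export
  covers summary tables (site intercepts, term edf/smoothing parameters,
  monthly variances), not the bases needed for bit-exact reload.
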