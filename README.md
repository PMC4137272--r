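# pmgamm

Two-stage penalized-spline generalized additive mixed models (GAMMs) for
spatio-temporal exposure modeling of particulate matter.

## What problem this solves

Epidemiologic studies of chronic particulate-matter exposure need monthly
outdoor concentrations of PM<sub>2.5</sub>, PM<sub>10</sub> and the coarse
fraction PM<sub>2.5–10</sub> at arbitrary locations (typically subject
residences) across a large domain and a multi-decade window — far beyond
what monitor networks observe directly. `pmgamm` implements a land-use
regression approach that combines geographic covariates, smoothed
meteorology, and spatial smoothing at two scales:

```
log y[i,t] = a + a[t,r] + sum_q d_q(X[i,q]) + sum_p f_{p,r}(Z[i,t,p])
             + g_{t,r}(s_i) + g(s_i) + b_i + e[i,t]
```

where `d_q` and `f_{p,r}` are one-dimensional penalized spline smooths of
time-invariant (elevation, urban land use, densities, road distance) and
time-varying (wind, temperature, precipitation, stagnation) covariates,
`g_{t,r}` is a monthly regional thin-plate surface, `g` a domain-wide
long-term surface, `b_i` a site random effect, and `e[i,t]` heteroscedastic
noise by region-month. Estimation is in two stages: regional back-fitting
of site intercepts / monthly intercepts / covariate smooths / monthly
surfaces (with 400 km boundary buffers), then a domain-wide spatial model
on the estimated site intercepts. A ratio-based variant reconstructs
historical PM<sub>2.5</sub> from predicted PM<sub>10</sub> (log-ratio
response, outlier screen at 1.5x predicted PM<sub>10</sub>, temporal smooth,
seasonal surfaces, ratio truncated at 1), and coarse mass is obtained by
subtraction with independence-based error propagation.

The package includes the penalized-spline engine (B-spline and
eigen-truncated thin-plate bases, GCV with an over-fit-guard multiplier,
edf caps, Wald tests), site-exclusive 10-fold cross-validation with the
full bias/precision metric set (CV R², spatial CV R², NMBF, NMEF, CVMAE,
major-axis slope, interval coverage), forward/backward covariate selection
with significance and a-priori sign screens, delta-method native-scale
uncertainty, and a synthetic-data generator that emulates multi-network
monitoring panels with known truth.

## Worked example

```r
library(pmgamm)

net  <- generate_network(n_sites = 150, n_regions = 3, seed = 1)
cov  <- generate_covariates(net, n_months = 24, seed = 1)
ds   <- generate_pm_panel(net, cov, pm_truth_config(target_r2 = 0.8), seed = 1)

spec <- make_model_spec("pm_direct",
  tv_covariates = c("temperature", "wind"),
  ti_covariates = c("elevation", "urban_lu"))
fit  <- fit_exposure_model(spec, ds)

fit$stage1$R1
#> Stage-1 fit, region R1: 72 sites (22 buffer), 24 months, converged in 5 sweeps
round(fit$stage2$edf, 2)
#> parametric  elevation   urban_lu      space
#>       1.00       2.22       1.73      14.68
sqrt(fit$stage2$sigma2_b)
#> [1] 0.056
```

Region R1's fit used 50 of its own sites plus 22 buffer sites from the
neighboring region. In stage 2 the elevation smooth used 2.2 effective
degrees of freedom (a gently curved decline), urban land use 1.7, and the
long-term spatial surface 14.7; the residual site SD on the log scale is
0.056 — the unexplained between-site variability `sigma_b`.

Site-exclusive cross-validation with a stratified report:

```r
folds <- assign_folds(unique(ds$sites$site), 10, seed = 1)
cv    <- run_cv(spec, ds, folds)
stratified_report(cv, list(region = cv$region))
#>   stratum_set stratum    n cv_r2 nmbf_pct cvmae nmef_pct spatial_cv_r2 pi_coverage
#> 1     overall     all 2892 0.745    -1.21  1.23     11.9         0.912       0.952
#> 2      region      R1   992 0.604    -1.40  1.25     11.9         0.741       0.963
#> 3      region      R2   914 0.764    -1.21  1.03     11.9         0.932       0.952
#> 4      region      R3   986 0.709    -1.03  1.40     11.9         0.889       0.940
```

Overall the model explains 74.5% of the monthly variance at left-out sites
(the generator's predictable structure accounts for 80%; the rest is the
cost of estimating monthly surfaces from ~50 sites each), 91% of the
between-site long-term variance, under-predicts by 1.2% on average (NMBF),
has a mean absolute error of 1.2 µg/m³, and its 95% prediction intervals
cover 95.2% of left-out observations.

Predictions with uncertainty at arbitrary site-months:

```r
pred <- predict_exposure(fit, ds$panel[1:5, c("site","x","y","region","month")],
                         data = ds)
pred[, c("native_mean", "native_se", "lo95", "hi95")]
```

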