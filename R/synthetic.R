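#' Synthetic monitoring networks, covariates and PM panels
#'
#' Generates data with the statistical structure the exposure models
#' assume: a clustered monitor network over contiguous planar regions,
#' geographic covariates (elevation, urban land use, population density,
#' distance to road, point-source density) and seasonal meteorology with
#' spatial correlation, and log-normal monthly PM concentrations driven by
#' smooth covariate effects, a long-term spatial field, regional monthly
#' spatial fields, site random effects and region-month heteroscedastic
#' noise — plus a coupled PM2.5:PM10 ratio process for the historical
#' reconstruction.  Every generator is a pure function of its configuration
#' and seed, and the generating truth is returned alongside the data so
#' estimation error can be separated from irreducible noise.
#'
#' @name pmgamm-synthetic
#' @keywords internal
NULL

# sum of Gaussian bumps: the package's stand-in for smooth spatial fields
make_bump_field <- function(n_bumps, xlim, ylim, amplitude, scale_range) {
  cx <- stats::runif(n_bumps, xlim[1], xlim[2])
  cy <- stats::runif(n_bumps, ylim[1], ylim[2])
  a <- stats::runif(n_bumps, -amplitude, amplitude)
  sc <- stats::runif(n_bumps, scale_range[1], scale_range[2])
  list(cx = cx, cy = cy, a = a, sc = sc)
}

eval_bump_field <- function(field, x, y) {
  out <- numeric(length(x))
  for (b in seq_along(field$a)) {
    d2 <- (x - field$cx[b])^2 + (y - field$cy[b])^2
    out <- out + field$a[b] * exp(-d2 / (2 * field$sc[b]^2))
  }
  out
}

#' Generate a synthetic monitoring network
#'
#' Regions tile a planar rectangle as vertical strips; sites are drawn from
#' a clustered point process (urban clusters plus rural background) so that
#' urban tertiles are meaningful.
#'
#' @param n_sites total number of sites (>= 10 per region).
#' @param n_regions number of contiguous regions (2-7 typical).
#' @param seed integer seed.
#' @param width,height domain size in km (default 3000 x 2000).
#' @param cluster_frac fraction of sites in urban clusters (default 0.6).
#' @return list `sites` (data frame `site`, `x`, `y`, `region`,
#'   `urbanness`, `urban_tertile`) and `geometry` (per-region rectangles).
#' @export
generate_network <- function(n_sites = 150, n_regions = 3, seed = 1,
                             width = 3000, height = 2000,
                             cluster_frac = 0.6) {
  if (n_sites < 10 * n_regions) stop("need at least 10 sites per region")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  strip <- width / n_regions
  geometry <- data.frame(
    region = paste0("R", seq_len(n_regions)),
    xmin = (seq_len(n_regions) - 1) * strip,
    xmax = seq_len(n_regions) * strip,
    ymin = 0, ymax = height
  )
  per_region <- rep(n_sites %/% n_regions, n_regions)
  extra <- n_sites - sum(per_region)
  if (extra > 0) per_region[seq_len(extra)] <- per_region[seq_len(extra)] + 1
  rows <- list()
  clusters <- list()
  for (r in seq_len(n_regions)) {
    n_r <- per_region[r]
    n_cl <- 2
    ccx <- stats::runif(n_cl, geometry$xmin[r] + 0.15 * strip,
      geometry$xmax[r] - 0.15 * strip)
    ccy <- stats::runif(n_cl, 0.15 * height, 0.85 * height)
    clusters[[r]] <- cbind(ccx, ccy)
    n_urban <- round(cluster_frac * n_r)
    ci <- sample(n_cl, n_urban, replace = TRUE)
    ux <- stats::rnorm(n_urban, ccx[ci], 60)
    uy <- stats::rnorm(n_urban, ccy[ci], 60)
    bx <- stats::runif(n_r - n_urban, geometry$xmin[r], geometry$xmax[r])
    by <- stats::runif(n_r - n_urban, 0, height)
    x <- pmin(pmax(c(ux, bx), geometry$xmin[r]), geometry$xmax[r])
    y <- pmin(pmax(c(uy, by), 0), height)
    rows[[r]] <- data.frame(
      x = x, y = y, region = geometry$region[r], stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, rows)
  sites$site <- sprintf("site%04d", seq_len(nrow(sites)))
  all_cl <- do.call(rbind, clusters)
  dmin <- apply(sites[, c("x", "y")], 1, function(p) {
    min(sqrt((all_cl[, 1] - p[1])^2 + (all_cl[, 2] - p[2])^2))
  })
  sites$urbanness <- exp(-dmin / 80)
  qs <- stats::quantile(sites$urbanness, c(1 / 3, 2 / 3))
  sites$urban_tertile <- cut(sites$urbanness,
    breaks = c(-Inf, qs, Inf),
    labels = c("low", "mid", "high")
  )
  sites <- sites[, c("site", "x", "y", "region", "urbanness",
    "urban_tertile")]
  rownames(sites) <- NULL
  list(sites = sites, geometry = geometry)
}

#' Generate synthetic geographic and meteorological covariates
#'
#' Site-level covariates: elevation (smooth field, m), urban land-use
#' fraction, population density (right-skewed, tied to urbanness),
#' distance to nearest road (right-skewed; a substantial share exceeds the
#' 500 m truncation point), and point-source emission density (sparse,
#' skewed).  Site-month covariates: temperature (deg C, 12-month cycle with
#' a latitude gradient), wind speed (m/s), precipitation depth, and air
#' stagnation (percent of stagnant days) — all with spatially correlated
#' fields and seasonal cycles.
#'
#' @param network result of [generate_network()].
#' @param n_months number of monthly periods.
#' @param seed integer seed.
#' @return list `X` (site-level data frame), `Z` (named list of site x
#'   month matrices), `months` (1..n_months).
#' @export
generate_covariates <- function(network, n_months = 24, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1)
  sites <- network$sites
  n <- nrow(sites)
  xlim <- range(network$geometry$xmin, network$geometry$xmax)
  ylim <- range(network$geometry$ymin, network$geometry$ymax)

  # broad orography plus substantial local relief: sites a few km apart
  # can differ by hundreds of meters, so elevation is far from a
  # deterministic function of the smooth spatial coordinates
  elev_field <- make_bump_field(10, xlim, ylim, 1200, c(200, 600))
  elev <- 600 + eval_bump_field(elev_field, sites$x, sites$y) +
    stats::rnorm(n, 0, 180)
  elev <- pmax(elev, 0)
  urban_lu <- pmin(pmax(
    0.85 * sites$urbanness + stats::rnorm(n, 0, 0.07), 0
  ), 1)
  pop_density <- exp(4 + 2.5 * sites$urbanness + stats::rnorm(n, 0, 0.8))
  dist_road <- exp(stats::rnorm(n, log(200) - 1.2 * sites$urbanness, 1.4))
  ps_raw <- exp(stats::rnorm(n, 1 + 1.5 * sites$urbanness, 1.0))
  point_source <- ifelse(stats::runif(n) < 0.35, 0, ps_raw)

  X <- data.frame(
    elevation = elev, urban_lu = urban_lu, pop_density = pop_density,
    dist_road = dist_road, point_source = point_source
  )
  rownames(X) <- sites$site

  month <- seq_len(n_months)
  phase <- 2 * pi * ((month - 1) %% 12) / 12
  lat <- (sites$y - mean(sites$y)) / max(diff(range(sites$y)), 1)
  t_field <- make_bump_field(6, xlim, ylim, 3, c(300, 800))
  t_sp <- eval_bump_field(t_field, sites$x, sites$y)
  temperature <- outer(lat * -8 + t_sp, rep(1, n_months)) +
    outer(rep(1, n), 12 - 11 * cos(phase)) +
    matrix(stats::rnorm(n * n_months, 0, 1.5), n, n_months)
  w_field <- make_bump_field(6, xlim, ylim, 1, c(300, 800))
  wind <- pmax(outer(3.5 + eval_bump_field(w_field, sites$x, sites$y),
    rep(1, n_months)) +
    outer(rep(1, n), 0.8 * cos(phase + 0.5)) +
    matrix(stats::rnorm(n * n_months, 0, 0.5), n, n_months), 0.3)
  p_field <- make_bump_field(6, xlim, ylim, 30, c(300, 800))
  precip <- pmax(outer(70 + eval_bump_field(p_field, sites$x, sites$y),
    rep(1, n_months)) +
    outer(rep(1, n), 25 * sin(phase)) +
    matrix(stats::rnorm(n * n_months, 0, 15), n, n_months), 0)
  s_field <- make_bump_field(6, xlim, ylim, 8, c(300, 800))
  stagnation <- pmin(pmax(
    outer(18 + eval_bump_field(s_field, sites$x, sites$y),
      rep(1, n_months)) +
      outer(rep(1, n), 9 * cos(phase)) +
      matrix(stats::rnorm(n * n_months, 0, 4), n, n_months), 0
  ), 95)
  dimnames_z <- list(sites$site, month)
  Z <- lapply(
    list(
      temperature = temperature, wind = wind, precip = precip,
      stagnation = stagnation
    ),
    function(m) {
      dimnames(m) <- dimnames_z
      m
    }
  )
  list(X = X, Z = Z, months = month)
}

#' PM-panel truth configuration
#'
#' Amplitudes of the generating components of the log-PM process and the
#' target explainable variance fraction.  Defaults give a panel whose
#' predictable structure explains about 80% of the native-scale variance,
#' with a 0.1-SD site random effect, regional monthly spatial fields and
#' region-month heteroscedastic noise.
#'
#' @param alpha overall log-scale intercept (log of ~10 ug/m3).
#' @param target_r2 explainable (predictable-structure) fraction of
#'   native-scale variance; the noise scale is calibrated to reach it.
#' @param sigma_b site random-effect SD (log scale).
#' @param sigma_e_base baseline observation noise SD before calibration.
#' @param sigma_st amplitude of the regional monthly spatial fields.
#' @param missing_rate completely-at-random missingness rate.
#' @param effect_scale multiplier on all covariate effects.
#' @return configuration list.
#' @export
pm_truth_config <- function(alpha = log(10), target_r2 = 0.8,
                            sigma_b = 0.1, sigma_e_base = 0.25,
                            sigma_st = 0.12, missing_rate = 0.1,
                            effect_scale = 1) {
  as.list(environment())
}

#' Generate a synthetic PM panel with known truth
#'
#' Draws a monthly log-normal PM panel
#' \eqn{\log y_{i,t} = \alpha + \alpha_t + \sum_q d^*_q(X_q) +
#'   \sum_p f^*_p(Z_p) + g^*(s) + g^*_{t,r}(s) + b_i + e_{i,t}}
#' with closed-form smooth effects, Gaussian-bump spatial fields, and
#' region-month heteroscedastic noise, then rescales the noise components
#' so the predictable structure explains `target_r2` of the native-scale
#' variance.  The returned truth object contains every component, so
#' estimation error can be computed exactly.
#'
#' @param network from [generate_network()].
#' @param covariates from [generate_covariates()].
#' @param config a [pm_truth_config()].
#' @param seed integer seed.
#' @return list of class `"pm_dataset"`: `panel` (site, x, y, region,
#'   month, value with missingness applied), `sites`, `geometry`, `X`,
#'   `Z`, and `truth` (component matrices, effect functions, noise scales,
#'   realized explainable fraction `r2_realized`).
#' @export
generate_pm_panel <- function(network, covariates,
                              config = pm_truth_config(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 2)
  sites <- network$sites
  n <- nrow(sites)
  X <- covariates$X
  Z <- covariates$Z
  months <- covariates$months
  n_m <- length(months)
  es <- config$effect_scale

  # closed-form covariate effects (log scale), centered over the sites
  d_funs <- list(
    elevation = function(v) es * -0.00025 * (v - 600),
    urban_lu = function(v) es * (0.35 * v + 0.15 * v^2)
  )
  f_funs <- list(
    temperature = function(v) es * (-0.008 * (v - 12) +
      0.0004 * (v - 12)^2),
    wind = function(v) es * -0.10 * (v - 3.5)
  )
  d_mat <- vapply(names(d_funs), function(q) {
    v <- d_funs[[q]](X[[q]])
    v - mean(v)
  }, numeric(n))
  f_arr <- lapply(names(f_funs), function(p) {
    m <- f_funs[[p]](Z[[p]])
    m - mean(m)
  })
  names(f_arr) <- names(f_funs)

  xlim <- range(network$geometry$xmin, network$geometry$xmax)
  ylim <- range(network$geometry$ymin, network$geometry$ymax)
  g_field <- make_bump_field(8, xlim, ylim, 0.25, c(250, 700))
  g_site <- eval_bump_field(g_field, sites$x, sites$y)
  g_site <- g_site - mean(g_site)

  regions <- unique(sites$region)
  alpha_t <- 0.15 * cos(2 * pi * ((months - 1) %% 12) / 12) +
    stats::rnorm(n_m, 0, 0.05)
  alpha_t <- alpha_t - mean(alpha_t)

  # Monthly spatial fields are continuous across the whole domain (real
  # pollutant fields do not jump at region boundaries; the regional
  # surfaces and buffers in the model are an estimation device) and
  # synoptic-scale broad: month-to-month anomalies are weather-driven,
  # with much coarser structure than the long-term mean surface.
  gt_fields <- list()
  gt_mat <- matrix(0, n, n_m)
  for (t in seq_len(n_m)) {
    fld <- make_bump_field(5, xlim, ylim, config$sigma_st * 2.2,
      c(500, 1200))
    gt_fields[[t]] <- fld
    v <- eval_bump_field(fld, sites$x, sites$y)
    gt_mat[, t] <- v - mean(v)
  }

  mu <- config$alpha +
    outer(rowSums(d_mat) + g_site, rep(1, n_m)) +
    Reduce(`+`, f_arr) +
    outer(rep(1, n), alpha_t) +
    gt_mat

  # region-month noise scale pattern (heteroscedastic)
  sig_e <- matrix(0, length(regions), n_m,
    dimnames = list(regions, months))
  for (r in seq_along(regions)) {
    sig_e[r, ] <- config$sigma_e_base *
      exp(stats::rnorm(n_m, 0, 0.2))
  }
  z_b <- stats::rnorm(n)
  z_e <- matrix(stats::rnorm(n * n_m), n, n_m)
  sig_e_obs <- sig_e[match(sites$region, regions), , drop = FALSE]

  # calibrate a single scale factor on (b, e) so the predictable structure
  # explains target_r2 of the native-scale variance
  nat_r2 <- function(s) {
    noise <- s * (config$sigma_b * z_b[row(z_e)] + sig_e_obs * z_e)
    stats::cor(as.numeric(exp(mu)), as.numeric(exp(mu + noise)))^2
  }
  f_obj <- function(s) nat_r2(s) - config$target_r2
  s_cal <- if (f_obj(1e-3) < 0) {
    warning("target explainable fraction unattainable; using minimal noise")
    1e-3
  } else {
    stats::uniroot(f_obj, c(1e-3, 20), tol = 1e-4)$root
  }
  b_i <- s_cal * config$sigma_b * z_b
  e_mat <- s_cal * sig_e_obs * z_e
  log_pm <- mu + outer(b_i, rep(1, n_m)) + e_mat

  panel <- data.frame(
    site = rep(sites$site, n_m),
    x = rep(sites$x, n_m),
    y = rep(sites$y, n_m),
    region = rep(sites$region, n_m),
    month = rep(months, each = n),
    value = as.numeric(exp(log_pm))
  )
  keep <- stats::runif(nrow(panel)) >= config$missing_rate
  panel <- panel[keep, , drop = FALSE]
  rownames(panel) <- NULL

  truth <- list(
    config = config, d_funs = d_funs, f_funs = f_funs,
    d_mat = d_mat, f_arr = f_arr, g_field = g_field, g_site = g_site,
    alpha = config$alpha, alpha_t = alpha_t,
    gt_fields = gt_fields, gt_mat = gt_mat,
    mu = mu, b = b_i, e = e_mat,
    sigma_b = s_cal * config$sigma_b,
    sigma_e = s_cal * sig_e,
    noise_scale = s_cal,
    r2_realized = nat_r2(s_cal)
  )
  structure(
    list(
      panel = panel, sites = sites, geometry = network$geometry,
      X = X, Z = Z, months = months, truth = truth
    ),
    class = "pm_dataset"
  )
}

#' Generate a coupled PM2.5:PM10 ratio panel
#'
#' Builds a PM2.5 panel from an existing PM10 dataset through a latent
#' log-ratio process with a temporal trend, an elevation effect, seasonal
#' regional spatial fields and site effects, squashed through a logistic
#' link so the true ratio lies in (0, 1).  A configured fraction of
#' records is contaminated with implausibly high PM2.5 (above 1.5x PM10)
#' to exercise the outlier-deletion rule.
#'
#' @param pm10_data a `"pm_dataset"` for PM10.
#' @param seed integer seed.
#' @param contamination fraction of records contaminated (default 0.003).
#' @param sigma_ratio log-scale noise SD of the observed ratio around its
#'   latent value (default 0.12).
#' @return list of class `"ratio_dataset"`: `panel` (site, ..., month,
#'   value = PM2.5), `truth` (latent ratio matrix, component functions,
#'   contaminated row ids), and the parent `pm10` reference.
#' @export
generate_ratio_panel <- function(pm10_data, seed = 1,
                                 contamination = 0.003,
                                 sigma_ratio = 0.12) {
  stopifnot(inherits(pm10_data, "pm_dataset"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 3)
  sites <- pm10_data$sites
  n <- nrow(sites)
  months <- pm10_data$months
  n_m <- length(months)
  xlim <- range(pm10_data$geometry$xmin, pm10_data$geometry$xmax)
  ylim <- range(pm10_data$geometry$ymin, pm10_data$geometry$ymax)

  h_fun <- function(t) 0.15 * sin(2 * pi * t / max(months)) - 0.002 * t
  d_elev <- function(v) -0.0002 * (v - 600)
  eta0 <- 0.4 # latent logit intercept: typical ratio ~ 0.6
  # seasonal fields, continuous across the domain (see generate_pm_panel)
  seas_fields <- list()
  seas_mat <- matrix(0, n, 4)
  for (s in 1:4) {
    fld <- make_bump_field(6, xlim, ylim, 0.2, c(250, 600))
    seas_fields[[s]] <- fld
    v <- eval_bump_field(fld, sites$x, sites$y)
    seas_mat[, s] <- v - mean(v)
  }
  b_i <- stats::rnorm(n, 0, 0.15)
  season_idx <- as.integer(month_season(months))
  eta <- eta0 + outer(d_elev(pm10_data$X$elevation) + b_i, rep(1, n_m)) +
    outer(rep(1, n), h_fun(months)) +
    seas_mat[, season_idx]
  ratio_true <- stats::plogis(eta)

  pm10 <- pm10_data$panel
  idx <- cbind(
    match(pm10$site, sites$site),
    match(pm10$month, months)
  )
  noise <- exp(stats::rnorm(nrow(pm10), 0, sigma_ratio))
  pm25 <- ratio_true[idx] * pm10$value * noise
  contam <- which(stats::runif(nrow(pm10)) < contamination)
  pm25[contam] <- pm10$value[contam] * stats::runif(length(contam), 1.7, 2.5)

  panel <- pm10
  panel$value <- pm25
  structure(
    list(
      panel = panel, sites = sites, geometry = pm10_data$geometry,
      X = pm10_data$X, Z = pm10_data$Z, months = months,
      truth = list(
        ratio = ratio_true, eta = eta, h_fun = h_fun, d_elev = d_elev,
        seas_fields = seas_fields, b = b_i, sigma_ratio = sigma_ratio,
        contaminated = contam
      ),
      pm10 = pm10_data
    ),
    class = "ratio_dataset"
  )
}

#' Generate a complete synthetic scenario
#'
#' One-call wrapper producing network, covariates and PM panel for the
#' standard study scenarios.
#'
#' @param scenario `"default"` (150 sites, 3 regions, 24 months),
#'   `"large"` (600 sites, 7 regions, 60 months), or `"historical"`
#'   (sparse early months for the evaluation-year CV design).
#' @param seed integer seed.
#' @param config optional [pm_truth_config()] override.
#' @return a `"pm_dataset"`.
#' @export
simulate_scenario <- function(scenario = c("default", "large",
                                "historical"),
                              seed = 1, config = pm_truth_config()) {
  scenario <- match.arg(scenario)
  dims <- switch(scenario,
    default = list(n_sites = 150, n_regions = 3, n_months = 24),
    large = list(n_sites = 600, n_regions = 7, n_months = 60),
    historical = list(n_sites = 150, n_regions = 3, n_months = 36)
  )
  net <- generate_network(dims$n_sites, dims$n_regions, seed = seed)
  cov <- generate_covariates(net, n_months = dims$n_months, seed = seed)
  ds <- generate_pm_panel(net, cov, config = config, seed = seed)
  if (scenario == "historical") {
    # few sites report early, many late: thin early months site-wise
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed + 9)
    early <- ds$panel$month <= dims$n_months / 2
    early_sites <- sample(unique(ds$panel$site),
      round(0.7 * length(unique(ds$panel$site))))
    drop <- early & ds$panel$site %in% early_sites
    ds$panel <- ds$panel[!drop, , drop = FALSE]
  }
  ds
}
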