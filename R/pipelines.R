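#' Exposure-model pipelines
#'
#' Composes meteorology smoothing, stage-1 regional back-fitting and the
#' stage-2 spatial model into the three model variants: direct log-PM
#' models (PM2.5 or PM10, monthly regional surfaces) and the historical
#' ratio model (response = log ratio of observed PM2.5 to predicted PM10,
#' temporal trend smooth, seasonal regional surfaces, predicted PM10 as an
#' additional time-varying covariate, outliers above 1.5x predicted PM10
#' deleted).  Predictions are produced on the native scale with
#' delta-method standard errors and 95% prediction intervals; predicted
#' ratios are truncated at one and coarse mass is the difference of the
#' PM10 and PM2.5 predictions with independence-based error propagation.
#'
#' @name pmgamm-pipelines
#' @keywords internal
NULL

#' Define an exposure-model specification
#'
#' @param variant `"pm_direct"`, `"pm10_direct"` or `"ratio"`.
#' @param tv_covariates time-varying covariate names (columns of the
#'   dataset's `Z` list).
#' @param ti_covariates time-invariant covariate names (columns of `X`).
#' @param transforms named character vector mapping covariates to
#'   `"log_shift"` or `"sqrt_shift"` (default: square-root-shift for
#'   elevation, log-shift for density-type covariates).
#' @param interactions time-invariant covariates given region-specific
#'   smooths in stage 2.
#' @param buffer_km stage-1 regional buffer (default 400).
#' @param gamma_spatial default spatial GCV multiplier (1.4).
#' @param sparse_regions regions fit with multiplier `gamma_sparse`.
#' @param gamma_sparse multiplier for sparse regions (1.8).
#' @param df_cap edf ceiling per 1-D smooth (6).
#' @param stage1 extra arguments passed to [stage1_config()].
#' @return `"model_spec"` list.  The ratio variant implies seasonal
#'   surfaces, the temporal trend smooth `h(t)`, and a `pm10_pred`
#'   time-varying covariate.
#' @export
make_model_spec <- function(variant = c("pm_direct", "pm10_direct",
                              "ratio"),
                            tv_covariates = c("temperature", "wind"),
                            ti_covariates = c("elevation", "urban_lu"),
                            transforms = c(
                              elevation = "sqrt_shift",
                              pop_density = "log_shift",
                              dist_road = "log_shift",
                              point_source = "log_shift"
                            ),
                            interactions = character(0),
                            buffer_km = 400, gamma_spatial = 1.4,
                            sparse_regions = character(0),
                            gamma_sparse = 1.8, df_cap = 6,
                            stage1 = list()) {
  variant <- match.arg(variant)
  ratio <- variant == "ratio"
  structure(
    list(
      variant = variant,
      tv_covariates = unique(c(
        tv_covariates,
        if (ratio) "pm10_pred"
      )),
      ti_covariates = ti_covariates,
      transforms = transforms, interactions = interactions,
      buffer_km = buffer_km, gamma_spatial = gamma_spatial,
      sparse_regions = sparse_regions, gamma_sparse = gamma_sparse,
      df_cap = df_cap,
      cadence = if (ratio) "seasonal" else "monthly",
      h_term = ratio,
      stage1 = stage1
    ),
    class = "model_spec"
  )
}

#' Remove ratio-model outliers
#'
#' Deletes records whose observed PM2.5 exceeds 1.5 times the predicted
#' PM10 (strict inequality: a record exactly at 1.5x is kept).
#'
#' @param pm25 observed PM2.5 values.
#' @param pm10_pred predicted PM10 aligned with `pm25`.
#' @param factor multiplier (default 1.5).
#' @return list `keep` (logical), `n_removed`.
#' @export
remove_ratio_outliers <- function(pm25, pm10_pred, factor = 1.5) {
  stopifnot(length(pm25) == length(pm10_pred))
  keep <- !(pm25 > factor * pm10_pred)
  list(keep = keep, n_removed = sum(!keep))
}

#' Clamp covariates to training ranges
#'
#' Prediction-time covariate values beyond their observed range among the
#' training monitoring sites are set to the appropriate minimum or maximum
#' — globally for time-invariant covariates, within each region for
#' time-varying covariates.
#'
#' @param values numeric vector of covariate values.
#' @param range training `c(min, max)` for these values (for regional
#'   clamping, pass the row's own region's range).
#' @return list `values` (clamped), `flag` (logical, TRUE where clamped).
#' @export
clamp_covariates <- function(values, range) {
  if (length(range) != 2 || any(!is.finite(range))) {
    stop("invalid training range")
  }
  cl <- pmin(pmax(values, range[1]), range[2])
  list(values = cl, flag = cl != values)
}

#' Fit an exposure model
#'
#' Runs the full two-stage pipeline for one model variant on a synthetic
#' (or identically structured) dataset: covariate transforms and training
#' ranges, regional stage-1 back-fitting with 400 km buffers, and the
#' domain-wide stage-2 spatial model on the site intercepts.  The ratio
#' variant requires a fitted PM10 model, whose predictions define the
#' response ratio, the outlier screen, and the `pm10_pred` covariate.
#'
#' @param spec a [make_model_spec()].
#' @param data a `"pm_dataset"` (or `"ratio_dataset"` for the ratio
#'   variant).
#' @param pm10_model a fitted `"exposure_model"` with variant
#'   `"pm10_direct"`; required for the ratio variant.
#' @param sites_subset optional site ids to fit on (cross-validation).
#' @param k_spatial2 optional stage-2 spatial basis dimension override.
#' @return object of class `"exposure_model"`.
#' @export
fit_exposure_model <- function(spec, data, pm10_model = NULL,
                               sites_subset = NULL, k_spatial2 = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ratio <- spec$variant == "ratio"
  if (ratio && is.null(pm10_model)) {
    stop("the ratio variant requires a fitted PM10 model ('pm10_model')")
  }
  sites <- data$sites
  panel <- data$panel
  if (!is.null(sites_subset)) {
    sites <- sites[sites$site %in% sites_subset, , drop = FALSE]
    panel <- panel[panel$site %in% sites_subset, , drop = FALSE]
  }

  # time-invariant covariates: transform and record global training ranges
  ti <- spec$ti_covariates
  X_t <- data.frame(row.names = sites$site)
  ti_meta <- list()
  for (q in ti) {
    raw <- data$X[sites$site, q]
    if (q == "dist_road") raw <- truncate_distance(raw)
    tr <- unname(spec$transforms[q])
    if (!is.na(tr)) {
      v <- if (tr == "log_shift") {
        log_shift_transform(raw)
      } else {
        sqrt_shift_transform(raw)
      }
      ti_meta[[q]] <- list(
        transform = attr(v, "transform"),
        min = attr(v, "min"), shift = attr(v, "shift")
      )
      v <- as.numeric(v)
    } else {
      v <- raw
      ti_meta[[q]] <- NULL
    }
    X_t[[q]] <- v
  }
  ti_ranges <- lapply(X_t, range)

  # response and time-varying covariates
  tv <- spec$tv_covariates
  Z_use <- data$Z[setdiff(tv, "pm10_pred")]
  n_removed <- 0L
  if (ratio) {
    pm10_hat <- predict_exposure(pm10_model,
      newdata = panel[, c("site", "x", "y", "region", "month")],
      data = data, observation = FALSE
    )$native_mean
    rr <- remove_ratio_outliers(panel$value, pm10_hat)
    n_removed <- rr$n_removed
    panel <- panel[rr$keep, , drop = FALSE]
    pm10_hat <- pm10_hat[rr$keep]
    panel$.y <- log(panel$value / pm10_hat)
    # predicted PM10 at every site-month, as a time-varying covariate
    n_m <- length(data$months)
    allsm <- data.frame(
      site = rep(sites$site, n_m), x = rep(sites$x, n_m),
      y = rep(sites$y, n_m), region = rep(sites$region, n_m),
      month = rep(data$months, each = nrow(sites)),
      stringsAsFactors = FALSE
    )
    p10 <- predict_exposure(pm10_model,
      newdata = allsm, data = data,
      observation = FALSE
    )$native_mean
    Z_use$pm10_pred <- matrix(p10,
      nrow = nrow(sites),
      dimnames = list(sites$site, data$months)
    )
  } else {
    panel$.y <- log(panel$value)
  }

  # per-region time-varying covariate training ranges
  tv_ranges <- list()
  for (r in unique(sites$region)) {
    in_r <- sites$region == r
    tv_ranges[[as.character(r)]] <- lapply(
      stats::setNames(nm = tv),
      function(p) range(Z_use[[p]][in_r, , drop = FALSE])
    )
  }

  reg_sets <- attach_buffer(sites, data$geometry, spec$buffer_km)
  stage1 <- list()
  for (r in names(reg_sets)) {
    rs <- reg_sets[[r]]
    pr <- panel[panel$site %in% rs$site, , drop = FALSE]
    pr$buffer <- rs$buffer[match(pr$site, rs$site)]
    rp <- data.frame(
      site = pr$site, x = pr$x, y = pr$y, month = pr$month,
      value = pr$.y, buffer = pr$buffer, stringsAsFactors = FALSE
    )
    zi <- cbind(match(pr$site, sites$site), match(pr$month, data$months))
    for (p in tv) rp[[p]] <- Z_use[[p]][zi]
    cfg_args <- spec$stage1
    cfg_args$gamma_spatial <- if (r %in% spec$sparse_regions) {
      spec$gamma_sparse
    } else {
      spec$gamma_spatial
    }
    cfg_args$h_term <- spec$h_term
    cfg_args$month_intercepts <- !spec$h_term
    cfg_args$seasonal <- spec$cadence == "seasonal"
    cfg <- do.call(stage1_config, cfg_args)
    stage1[[r]] <- backfit_region(rp, tv, cfg, region = r)
  }

  u_hat <- do.call(rbind, lapply(stage1, extract_site_intercepts))
  u_hat$region <- sites$region[match(u_hat$site, sites$site)]
  X_s2 <- X_t[u_hat$site, , drop = FALSE]
  stage2 <- fit_stage2(u_hat, X_s2,
    covariates = ti,
    interactions = spec$interactions, k_spatial = k_spatial2,
    df_cap = spec$df_cap
  )

  structure(
    list(
      spec = spec, stage1 = stage1, stage2 = stage2,
      ti_meta = ti_meta, ti_ranges = ti_ranges, tv_ranges = tv_ranges,
      months = data$months, n_outliers_removed = n_removed,
      pm10_model = if (ratio) pm10_model,
      site_roster = sites$site
    ),
    class = "exposure_model"
  )
}

# assemble clamped, transformed covariates for prediction rows
prepare_prediction_frame <- function(model, newdata, data) {
  nd <- newdata
  n <- nrow(nd)
  clamped <- rep(FALSE, n)
  for (q in model$spec$ti_covariates) {
    raw <- if (q %in% names(nd)) nd[[q]] else data$X[nd$site, q]
    if (q == "dist_road") raw <- truncate_distance(raw)
    v <- if (!is.null(model$ti_meta[[q]])) {
      apply_transform(raw, model$ti_meta[[q]])
    } else {
      raw
    }
    cl <- clamp_covariates(v, model$ti_ranges[[q]])
    nd[[q]] <- cl$values
    clamped <- clamped | cl$flag
  }
  tv <- model$spec$tv_covariates
  zi <- NULL
  for (p in tv) {
    v <- if (p %in% names(nd)) {
      nd[[p]]
    } else if (p == "pm10_pred") {
      predict_exposure(model$pm10_model,
        newdata = newdata[, c("site", "x", "y", "region", "month")],
        data = data, observation = FALSE
      )$native_mean
    } else {
      if (is.null(zi)) {
        zi <- cbind(
          match(nd$site, rownames(data$Z[[1]])),
          match(nd$month, data$months)
        )
      }
      data$Z[[p]][zi]
    }
    for (r in unique(as.character(nd$region))) {
      rr <- model$tv_ranges[[r]]
      if (is.null(rr)) stop(sprintf("no training range for region %s", r))
      in_r <- as.character(nd$region) == r
      cl <- clamp_covariates(v[in_r], rr[[p]])
      v[in_r] <- cl$values
      clamped[in_r] <- clamped[in_r] | cl$flag
    }
    nd[[p]] <- v
  }
  nd$.clamped <- clamped
  nd
}

#' Log-scale prediction from a fitted exposure model
#'
#' Evaluates the composed model at new site-months: the stage-2 component
#' (global intercept, time-invariant covariate smooths, domain surface)
#' plus the stage-1 component for the row's region (monthly intercept,
#' time-varying covariate smooths, monthly or seasonal surface, temporal
#' trend).  The prediction variance adds the stage-2 posterior variance,
#' the surface variance and the monthly-intercept variance, treating
#' stages as independent; the observation-level variance additionally adds
#' the site-effect variance \eqn{\sigma^2_b} and the region-month residual
#' variance.
#'
#' @param model an `"exposure_model"`.
#' @param newdata data frame with `site`, `x`, `y`, `region`, `month` and
#'   (optionally) covariate columns; covariates absent from `newdata` are
#'   looked up in `data`.
#' @param data the dataset the covariates come from (defaults to covariate
#'   columns present in `newdata`).
#' @return data frame `mu_log`, `se_log` (mean prediction), `se_obs`
#'   (observation level), `clamped`.
#' @export
predict_log <- function(model, newdata, data = NULL) {
  stopifnot(inherits(model, "exposure_model"))
  nd <- prepare_prediction_frame(model, newdata, data)
  if (!all(as.character(nd$region) %in% names(model$stage1))) {
    stop("rows in regions without a stage-1 fit")
  }
  s2 <- stage2_component(model$stage2, nd)
  mu <- s2$mean
  v_mean <- s2$se^2
  v_obs_extra <- rep(model$stage2$sigma2_b, nrow(nd))
  for (r in unique(as.character(nd$region))) {
    in_r <- as.character(nd$region) == r
    s1 <- stage1_component(model$stage1[[r]], nd[in_r, , drop = FALSE])
    mu[in_r] <- mu[in_r] + s1$mean
    v_mean[in_r] <- v_mean[in_r] + s1$var
    v_obs_extra[in_r] <- v_obs_extra[in_r] + s1$sigma2_e
  }
  data.frame(
    mu_log = mu, se_log = sqrt(v_mean),
    se_obs = sqrt(v_mean + v_obs_extra),
    clamped = nd$.clamped
  )
}

#' Native-scale mean and standard error by the delta method
#'
#' First-order delta method for the exponential back-transform:
#' `mean = exp(mu)`, `se = exp(mu) * se_log`.
#'
#' @param mu_log log-scale mean.
#' @param se_log log-scale standard error (>= 0).
#' @return list `mean`, `se`.
#' @export
predict_native <- function(mu_log, se_log) {
  if (any(se_log < 0, na.rm = TRUE)) stop("negative log-scale SE")
  m <- exp(mu_log)
  list(mean = m, se = m * se_log)
}

#' Combine a predicted ratio with predicted PM10
#'
#' Native-scale PM2.5 from the historical ratio model: the predicted
#' PM2.5:PM10 ratio is truncated at one (flagged), multiplied by predicted
#' PM10, and the variance combines both sources under independence:
#' `var = ratio^2 var(PM10) + PM10^2 var(ratio)`.  The 95% interval is a
#' native-scale normal interval floored at zero.
#'
#' @param ratio_mean,ratio_se native-scale ratio prediction and SE.
#' @param pm10_mean,pm10_se native-scale PM10 prediction and SE.
#' @return data frame `mean`, `se`, `lo95`, `hi95`, `ratio_truncated`.
#' @export
combine_ratio_pm10 <- function(ratio_mean, ratio_se, pm10_mean, pm10_se) {
  if (any(c(ratio_mean, ratio_se, pm10_mean, pm10_se) < 0, na.rm = TRUE)) {
    stop("negative native-scale inputs")
  }
  trunc <- ratio_mean > 1
  r <- pmin(ratio_mean, 1)
  m <- r * pm10_mean
  se <- sqrt(r^2 * pm10_se^2 + pm10_mean^2 * ratio_se^2)
  z <- stats::qnorm(0.975)
  data.frame(
    mean = m, se = se,
    lo95 = pmax(m - z * se, 0), hi95 = m + z * se,
    ratio_truncated = trunc
  )
}

#' Coarse-fraction (PM2.5-10) prediction
#'
#' PM10 minus PM2.5 on the native scale, with independence-based error
#' propagation (`se = sqrt(se10^2 + se25^2)`); non-positive means are
#' flagged for exclusion from validation summaries but retained in output.
#'
#' @param pm10_mean,pm10_se native-scale PM10 prediction and SE.
#' @param pm25_mean,pm25_se native-scale PM2.5 prediction and SE.
#' @return data frame `mean`, `se`, `lo95`, `hi95`, `nonpositive`.
#' @export
coarse_fraction <- function(pm10_mean, pm10_se, pm25_mean, pm25_se) {
  m <- pm10_mean - pm25_mean
  se <- sqrt(pm10_se^2 + pm25_se^2)
  z <- stats::qnorm(0.975)
  data.frame(
    mean = m, se = se, lo95 = m - z * se, hi95 = m + z * se,
    nonpositive = m <= 0
  )
}

#' Native-scale prediction with intervals
#'
#' Full prediction chain for any variant.  Direct variants exponentiate the
#' log-scale prediction (intervals are exponentiated log-scale normal
#' intervals); the ratio variant combines the truncated native ratio with
#' the PM10 model's native prediction.
#'
#' @param model an `"exposure_model"`.
#' @param newdata prediction rows (see [predict_log()]).
#' @param data source dataset for covariate lookup.
#' @param observation if `TRUE` (default) intervals are observation-level
#'   (include \eqn{\sigma^2_b} and \eqn{\sigma^2_e}); otherwise they cover
#'   the mean prediction only.
#' @return data frame with log- and native-scale means, SEs, and 95%
#'   bounds; for the ratio variant also the truncation flag.
#' @export
predict_exposure <- function(model, newdata, data = NULL,
                             observation = TRUE) {
  pl <- predict_log(model, newdata, data)
  se_use <- if (observation) pl$se_obs else pl$se_log
  z <- stats::qnorm(0.975)
  if (model$spec$variant != "ratio") {
    nat <- predict_native(pl$mu_log, se_use)
    out <- data.frame(
      mu_log = pl$mu_log, se_log = pl$se_log, se_obs = pl$se_obs,
      native_mean = nat$mean, native_se = nat$se,
      lo95 = exp(pl$mu_log - z * se_use),
      hi95 = exp(pl$mu_log + z * se_use),
      clamped = pl$clamped
    )
    return(out)
  }
  rat <- predict_native(pl$mu_log, se_use)
  p10 <- predict_exposure(model$pm10_model,
    newdata = newdata[, c("site", "x", "y", "region", "month")],
    data = data, observation = observation
  )
  comb <- combine_ratio_pm10(rat$mean, rat$se, p10$native_mean,
    p10$native_se)
  data.frame(
    mu_log = pl$mu_log, se_log = pl$se_log, se_obs = pl$se_obs,
    ratio_mean = pmin(rat$mean, 1), ratio_se = rat$se,
    native_mean = comb$mean, native_se = comb$se,
    lo95 = comb$lo95, hi95 = comb$hi95,
    ratio_truncated = comb$ratio_truncated,
    clamped = pl$clamped
  )
}

#' Site-exclusive cross-validation of an exposure model
#'
#' For each fold 1..9, refits the full pipeline without the fold's sites
#' and predicts the left-out site-months; the reserved fold (10) is never
#' used for fitting and is not predicted here (see the honesty check in
#' the validation tooling).  For the ratio variant the PM10 model is refit
#' on the same training sites in each fold.
#'
#' @param spec a [make_model_spec()].
#' @param data the dataset.
#' @param folds a `"fold_assignment"` from [assign_folds()] or
#'   [build_year2000_design()].
#' @param pm10_spec specification for the per-fold PM10 refit (ratio
#'   variant only).
#' @param eval_months restrict evaluation to these months (the
#'   evaluation-year design); default all.
#' @param observation observation-level intervals (default TRUE).
#' @param reserved_in_fit include reserved-fold sites in each training set
#'   (default TRUE: each fold model is fit to all data except the left-out
#'   fold; set FALSE during covariate selection, where the reserved set
#'   must stay untouched).
#' @param ... passed on to [fit_exposure_model()].
#' @return data frame `site`, `month`, `region`, `fold`, `observed`,
#'   `predicted`, `lo95`, `hi95`, `mu_log`, `se_obs`.
#' @export
run_cv <- function(spec, data, folds, pm10_spec = NULL,
                   eval_months = NULL, observation = TRUE,
                   reserved_in_fit = TRUE, ...) {
  stopifnot(inherits(folds, "fold_assignment"))
  panel <- data$panel
  out <- list()
  active <- sort(unique(folds$fold[!folds$reserved]))
  for (f in active) {
    test_sites <- folds$site[folds$fold == f]
    drop_sites <- if (reserved_in_fit) {
      test_sites
    } else {
      c(test_sites, folds$site[folds$reserved])
    }
    train_sites <- setdiff(unique(data$sites$site), drop_sites)
    p10 <- NULL
    if (spec$variant == "ratio") {
      if (is.null(pm10_spec)) stop("ratio CV needs 'pm10_spec'")
      p10 <- fit_exposure_model(pm10_spec, data$pm10,
        sites_subset = train_sites, ...
      )
    }
    fit <- tryCatch(
      fit_exposure_model(spec, data,
        pm10_model = p10,
        sites_subset = train_sites, ...
      ),
      error = function(e) {
        stop(sprintf("fold %d refit failed: %s", f, conditionMessage(e)))
      }
    )
    test_rows <- panel[panel$site %in% test_sites, , drop = FALSE]
    if (!is.null(eval_months)) {
      test_rows <- test_rows[test_rows$month %in% eval_months, ,
        drop = FALSE]
    }
    if (nrow(test_rows) == 0) next
    pr <- predict_exposure(fit,
      newdata = test_rows[, c("site", "x", "y", "region", "month")],
      data = data, observation = observation
    )
    out[[length(out) + 1]] <- data.frame(
      site = test_rows$site, month = test_rows$month,
      region = test_rows$region, fold = f,
      observed = test_rows$value, predicted = pr$native_mean,
      lo95 = pr$lo95, hi95 = pr$hi95,
      mu_log = pr$mu_log, se_obs = pr$se_obs
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Save / load a fitted exposure model
#'
#' Round-trip serialization preserving predictions bit-for-bit.
#'
#' @param model an `"exposure_model"`.
#' @param path file path.
#' @export
save_exposure_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_exposure_model
#' @export
load_exposure_model <- function(path) {
  readRDS(path)
}

#' Export model summary tables as delimited text
#'
#' Writes the human-readable fit summaries (site intercepts, per-term
#' smoothing parameters / edf / Wald p-values, region-month residual
#' variances) into a directory of tab-separated files.
#'
#' @param model an `"exposure_model"`.
#' @param dir output directory (created if needed).
#' @export
export_model_summary <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  u <- do.call(rbind, lapply(names(model$stage1), function(r) {
    cbind(region = r, extract_site_intercepts(model$stage1[[r]]))
  }))
  utils::write.table(u, file.path(dir, "site_intercepts.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  tr <- do.call(rbind, lapply(names(model$stage1), function(r) {
    s1 <- model$stage1[[r]]
    data.frame(
      region = r, month = names(s1$sigma2_e),
      sigma2_e = as.numeric(s1$sigma2_e),
      alpha = as.numeric(s1$alpha[names(s1$sigma2_e)])
    )
  }))
  utils::write.table(tr, file.path(dir, "monthly_intercepts.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  s2 <- model$stage2
  tn <- names(s2$edf)
  terms <- data.frame(
    term = tn, edf = as.numeric(s2$edf),
    lambda = as.numeric(s2$fit$lambda[match(tn, names(s2$fit$lambda))]),
    wald_p = as.numeric(s2$wald_p[match(tn, names(s2$wald_p))]),
    row.names = NULL
  )
  utils::write.table(terms, file.path(dir, "stage2_terms.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' Read / write monitoring panels as delimited text
#'
#' @param panel data frame (site, x, y, region, month, value, ...).
#' @param path file path (tab-separated).
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE)
}
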