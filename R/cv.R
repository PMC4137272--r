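#' Cross-validation design and evaluation metrics
#'
#' Model validation uses 10-fold *site-exclusive* cross-validation: whole
#' monitoring sites (all their months) are assigned at random to one of 10
#' sets; set 10 is reserved during covariate selection to detect
#' selection-induced over-fitting, and folds 1-9 are left out in turn.
#' Predictive accuracy is summarized on the native concentration scale by
#' the squared Pearson correlation of left-out observations and predictions
#' (CV R2; the spatial version first averages to one long-term mean per
#' site), and bias/precision by the normalized mean bias and error factors
#' (NMBF / NMEF), the mean absolute prediction error (CVMAE), the
#' major-axis slope of log observations on log predictions, and 95%
#' prediction-interval coverage.
#'
#' @name pmgamm-cv
#' @keywords internal
NULL

#' Assign sites to cross-validation folds
#'
#' Uniform random site-level partition into `n_folds` sets, deterministic
#' given `seed`.  Fold `n_folds` is flagged as the reserved set.
#'
#' @param sites vector of site identifiers.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return data frame `site`, `fold`, `reserved` of class
#'   `"fold_assignment"`.
#' @export
assign_folds <- function(sites, n_folds = 10, seed = 1) {
  sites <- unique(sites)
  if (length(sites) < n_folds) stop("fewer sites than folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(sites)))
  structure(
    data.frame(
      site = sites, fold = fold, reserved = fold == n_folds,
      stringsAsFactors = FALSE
    ),
    class = c("fold_assignment", "data.frame"),
    seed = seed, design = "standard"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build the evaluation-year cross-validation design
#'
#' For the historical reconstruction the data are too sparse before the
#' evaluation year, so cross-validation is confined to one well-monitored
#' year: qualifying sites must report at least `min_year_obs` monthly
#' values inside the evaluation year and at least `min_total_obs` overall.
#' A random subset of qualifying sites is withheld from CV entirely (to
#' keep the evaluation-year site density comparable to the sparse years);
#' among 25 candidate withholdings drawn under successive seeds, the one
#' with the best spatial spread (largest minimum nearest-neighbor distance
#' among retained sites) is kept.  The remaining qualifying sites are
#' partitioned into 10 folds.
#'
#' @param panel data frame with `site`, `x`, `y`, `month` (and observed
#'   values; rows are site-months with data).
#' @param eval_months month indices forming the evaluation year.
#' @param seed integer seed.
#' @param min_year_obs,min_total_obs qualification thresholds (10 and 70).
#' @param withhold_frac fraction of qualifying sites withheld from CV
#'   (default 0.25).
#' @param n_folds number of folds (default 10).
#' @return list `folds` (a `"fold_assignment"` over CV sites), `withheld`
#'   (site ids kept for fitting only), `qualifying` (all qualifying ids).
#' @export
build_year2000_design <- function(panel, eval_months, seed = 1,
                                  min_year_obs = 10, min_total_obs = 70,
                                  withhold_frac = 0.25, n_folds = 10) {
  stopifnot(all(c("site", "month") %in% names(panel)))
  in_year <- panel$month %in% eval_months
  if (!any(in_year)) stop("panel does not span the evaluation year")
  n_year <- table(panel$site[in_year])
  n_tot <- table(panel$site)
  qual <- names(n_year)[n_year >= min_year_obs &
    n_tot[names(n_year)] >= min_total_obs]
  if (length(qual) == 0) stop("no qualifying sites")
  sites_xy <- panel[!duplicated(panel$site), c("site", "x", "y")]
  rownames(sites_xy) <- sites_xy$site
  n_wh <- floor(withhold_frac * length(qual))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  best <- NULL
  best_score <- -Inf
  for (trial in seq_len(25)) {
    set.seed(seed * 1000 + trial)
    wh <- if (n_wh > 0) sample(qual, n_wh) else character(0)
    keep <- setdiff(qual, wh)
    if (length(keep) < n_folds) next
    xy <- sites_xy[keep, c("x", "y")]
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    score <- min(apply(d, 1, min))
    if (score > best_score) {
      best_score <- score
      best <- wh
    }
  }
  if (is.null(best)) stop("withholding left fewer sites than folds")
  keep <- setdiff(qual, best)
  folds <- assign_folds(keep, n_folds = n_folds, seed = seed)
  attr(folds, "design") <- "year2000"
  list(folds = folds, withheld = best, qualifying = qual)
}

#' Monthly and spatial cross-validation R-squared
#'
#' Squared Pearson correlation between left-out observations and model
#' predictions on the native concentration scale.  The spatial version
#' first collapses both series to one long-term mean per site.
#'
#' @param observed,predicted paired native-scale values.
#' @param sites site identifiers (spatial version).
#' @return squared correlation, or `NA` if either vector is degenerate.
#' @export
cv_r2 <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) {
    return(NA_real_)
  }
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(observed[ok], predicted[ok])^2
}

#' @rdname cv_r2
#' @export
spatial_cv_r2 <- function(observed, predicted, sites) {
  ok <- is.finite(observed) & is.finite(predicted)
  ob <- tapply(observed[ok], sites[ok], mean)
  pr <- tapply(predicted[ok], sites[ok], mean)
  cv_r2(as.numeric(ob), as.numeric(pr))
}

#' Normalized mean bias/error factors and CVMAE
#'
#' Symmetric relative bias and error metrics: with \eqn{S_M = \sum M} and
#' \eqn{S_O = \sum O}, when \eqn{\bar M \ge \bar O} the normalized mean
#' bias factor is \eqn{S_M/S_O - 1} and the error factor
#' \eqn{\sum|M - O| / S_O}; otherwise \eqn{1 - S_O/S_M} and
#' \eqn{\sum|M - O| / S_M}.  Both are reported in percent, so a model
#' over-predicting by a factor of two scores +100% and under-predicting by
#' a factor of two scores -100%.  CVMAE is the plain mean absolute
#' prediction error in concentration units.
#'
#' @param observed,predicted paired native-scale values with positive
#'   totals.
#' @return list `nmbf`, `nmef` (percent), `cvmae`.
#' @export
bias_error_metrics <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  O <- observed[ok]
  M <- predicted[ok]
  if (length(O) == 0 || sum(O) <= 0 || sum(M) <= 0) {
    return(list(nmbf = NA_real_, nmef = NA_real_, cvmae = NA_real_))
  }
  so <- sum(O)
  sm <- sum(M)
  sae <- sum(abs(M - O))
  if (mean(M) >= mean(O)) {
    nmbf <- sm / so - 1
    nmef <- sae / so
  } else {
    nmbf <- 1 - so / sm
    nmef <- sae / sm
  }
  list(nmbf = 100 * nmbf, nmef = 100 * nmef, cvmae = mean(abs(M - O)))
}

#' Major-axis regression of log observations on log predictions
#'
#' Line through the first principal axis of the centered bivariate cloud
#' (both variables treated as error-prone): the slope is the direction of
#' the leading eigenvector of the 2x2 covariance matrix, oriented positive
#' when the covariance is positive.
#'
#' @param x predictor values (here natural-log model predictions).
#' @param y response values (natural-log left-out observations).
#' @return list `intercept`, `slope`.
#' @export
major_axis_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    return(list(intercept = NA_real_, slope = NA_real_))
  }
  V <- stats::cov(cbind(x, y))
  if (all(abs(V) < 1e-300)) {
    return(list(intercept = NA_real_, slope = NA_real_))
  }
  eg <- eigen(V, symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (abs(v[1]) < 1e-14) {
    return(list(intercept = NA_real_, slope = Inf))
  }
  slope <- v[2] / v[1]
  if (V[1, 2] > 0 && slope < 0) slope <- -slope
  list(intercept = mean(y) - slope * mean(x), slope = slope)
}

#' Prediction-interval coverage
#'
#' Fraction of observations falling inside their prediction intervals.
#'
#' @param observed observations.
#' @param lower,upper interval bounds (must satisfy `lower <= upper`).
#' @return coverage proportion.
#' @export
pi_coverage <- function(observed, lower, upper) {
  if (any(lower > upper, na.rm = TRUE)) stop("intervals not well-ordered")
  ok <- is.finite(observed) & is.finite(lower) & is.finite(upper)
  mean(observed[ok] >= lower[ok] & observed[ok] <= upper[ok])
}

#' Mean within-site residual autocorrelation
#'
#' Within-site autocorrelation of model residuals, averaged across sites at
#' each lag — the diagnostic for temporal dependence unaccounted for by the
#' monthly terms.
#'
#' @param residuals residual vector.
#' @param sites site identifier per residual.
#' @param months month index per residual (series are ordered by month).
#' @param max_lag maximum lag (default 15).
#' @param min_len sites with fewer than `max_lag + 5` residuals are
#'   skipped.
#' @return data frame `lag`, `acf` (NA when no site qualifies or the series
#'   are constant).
#' @export
residual_acf <- function(residuals, sites, months, max_lag = 15,
                         min_len = max_lag + 5) {
  out <- matrix(NA_real_, 0, max_lag)
  for (s in unique(sites)) {
    idx <- which(sites == s)
    if (length(idx) < min_len) next
    r <- residuals[idx][order(months[idx])]
    if (stats::sd(r) == 0) next
    a <- stats::acf(r, lag.max = max_lag, plot = FALSE)$acf[-1]
    out <- rbind(out, as.numeric(a))
  }
  data.frame(
    lag = seq_len(max_lag),
    acf = if (nrow(out) > 0) colMeans(out, na.rm = TRUE) else
      rep(NA_real_, max_lag)
  )
}

#' Stratified cross-validation report
#'
#' Computes every validation metric overall and within strata (region,
#' season, urban tertile, ...).  Records flagged for exclusion (negative
#' predicted or observed coarse mass) are removed from the metrics and
#' counted as `n_excluded`.
#'
#' @param cv_pred data frame with columns `site`, `month`, `observed`,
#'   `predicted`, `lo95`, `hi95` and optionally `exclude` (logical) and
#'   `model_fitted` (in-sample fitted values for the model R2 column).
#' @param strata named list mapping stratum-set names to a factor/vector
#'   aligned with `cv_pred` rows; the report always includes an `overall`
#'   stratum.
#' @return data frame of class `"cv_report"`, one row per stratum level.
#' @export
stratified_report <- function(cv_pred, strata = list()) {
  stopifnot(all(c("site", "observed", "predicted") %in% names(cv_pred)))
  excl <- if ("exclude" %in% names(cv_pred)) {
    cv_pred$exclude
  } else {
    rep(FALSE, nrow(cv_pred))
  }
  excl <- excl | !is.finite(cv_pred$observed) |
    !is.finite(cv_pred$predicted)
  strata <- c(list(overall = rep("all", nrow(cv_pred))), strata)
  rows <- list()
  for (sn in names(strata)) {
    lab <- strata[[sn]]
    for (lv in unique(as.character(lab))) {
      in_s <- as.character(lab) == lv
      use <- in_s & !excl
      n_use <- sum(use)
      row <- data.frame(
        stratum_set = sn, stratum = lv,
        n = n_use, n_excluded = sum(in_s & excl),
        model_r2 = NA_real_, cv_r2 = NA_real_, ma_intercept = NA_real_,
        ma_slope = NA_real_, nmbf_pct = NA_real_, cvmae = NA_real_,
        nmef_pct = NA_real_, spatial_cv_r2 = NA_real_,
        pi_coverage = NA_real_
      )
      if (n_use >= 3) {
        O <- cv_pred$observed[use]
        M <- cv_pred$predicted[use]
        row$cv_r2 <- cv_r2(O, M)
        row$spatial_cv_r2 <- spatial_cv_r2(O, M, cv_pred$site[use])
        bm <- bias_error_metrics(O, M)
        row$nmbf_pct <- bm$nmbf
        row$nmef_pct <- bm$nmef
        row$cvmae <- bm$cvmae
        pos <- O > 0 & M > 0
        ma <- major_axis_fit(log(M[pos]), log(O[pos]))
        row$ma_intercept <- ma$intercept
        row$ma_slope <- ma$slope
        if ("model_fitted" %in% names(cv_pred)) {
          row$model_r2 <- cv_r2(O, cv_pred$model_fitted[use])
        }
        if (all(c("lo95", "hi95") %in% names(cv_pred))) {
          row$pi_coverage <- pi_coverage(
            O, cv_pred$lo95[use], cv_pred$hi95[use]
          )
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Write a cross-validation report as a delimited table
#'
#' @param report a `"cv_report"`.
#' @param path output file path (tab-separated).
#' @export
write_cv_report <- function(report, path) {
  utils::write.table(report, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
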