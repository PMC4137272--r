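#' Covariate selection with cross-validated screening
#'
#' Mirrors the model-development procedure: starting from a base term set,
#' (1) each time-varying term is dropped unless it improves monthly CV R2;
#' (2) time-invariant candidates are added greedily, keeping the set with
#' the highest spatial CV R2; (3) Wald-insignificant terms (p > 0.05) are
#' removed; (4) candidates whose fitted effect direction contradicts the
#' a-priori expected physical direction are dropped.  Every decision is
#' recorded in an audit ledger.
#'
#' @name pmgamm-selection
#' @keywords internal
NULL

#' Build a stage-2 cross-validation harness
#'
#' Returns a function evaluating a time-invariant term set by
#' site-exclusive CV of the stage-2 model on fixed stage-1 intercepts:
#' the stage-1 fit does not depend on which time-invariant covariates
#' enter stage 2, so candidate models only refit the (cheap) second stage.
#' Monthly CV R2 is computed by combining the per-fold stage-2 prediction
#' with the full-fit stage-1 monthly components.
#'
#' @param u_hat site-intercept table (`site`, `x`, `y`, `u`, optionally
#'   `region`).
#' @param X time-invariant covariate data frame (rows aligned).
#' @param folds a `"fold_assignment"` over the sites.
#' @param stage1_monthly optional data frame (`site`, `month`,
#'   `observed_native`, `stage1_mean`) enabling the monthly CV R2 metric.
#' @param ... further arguments to [fit_stage2()].
#' @return function(`ti_terms`) returning list `spatial_r2`,
#'   `monthly_r2` (NA without `stage1_monthly`), `u_pred`.
#' @export
make_stage2_cv_harness <- function(u_hat, X, folds,
                                   stage1_monthly = NULL, ...) {
  force(u_hat)
  force(X)
  force(folds)
  function(ti_terms) {
    u_pred <- rep(NA_real_, nrow(u_hat))
    for (f in sort(unique(folds$fold[!folds$reserved]))) {
      test_sites <- folds$site[folds$fold == f]
      tr <- !(u_hat$site %in% test_sites) &
        !(u_hat$site %in% folds$site[folds$reserved])
      te <- u_hat$site %in% test_sites
      fit <- fit_stage2(u_hat[tr, , drop = FALSE],
        X[tr, , drop = FALSE],
        covariates = ti_terms, ...
      )
      pr <- stage2_component(fit, cbind(
        u_hat[te, , drop = FALSE],
        X[te, , drop = FALSE]
      ))
      u_pred[te] <- pr$mean
    }
    ok <- !is.na(u_pred)
    spatial_r2 <- cv_r2(exp(u_hat$u[ok]), exp(u_pred[ok]))
    monthly_r2 <- NA_real_
    if (!is.null(stage1_monthly)) {
      sm <- stage1_monthly
      up <- u_pred[match(sm$site, u_hat$site)]
      pred <- exp(up + sm$stage1_mean)
      monthly_r2 <- cv_r2(sm$observed_native, pred)
    }
    list(
      spatial_r2 = spatial_r2, monthly_r2 = monthly_r2, u_pred = u_pred
    )
  }
}

#' Select covariates for the stage-2 model
#'
#' @param base_ti character vector of base time-invariant covariates (may
#'   be empty).
#' @param candidates_ti candidate time-invariant covariates to consider
#'   adding.
#' @param harness evaluation function from [make_stage2_cv_harness()] (or
#'   any function with the same contract).
#' @param u_hat,X data for the final full fit and the Wald/sign screens.
#' @param base_tv,tv_harness optional: time-varying base terms and a
#'   function(`tv_terms`) returning `list(monthly_r2 = ...)` for the drop
#'   phase; when omitted the drop phase records only that it was skipped.
#' @param expected_sign named vector of `+1` / `-1` expected effect
#'   directions (optional; covariates without an entry skip the sign
#'   screen).
#' @param threshold minimum CV-R2 improvement to keep/add a term
#'   (default 0.002).
#' @param alpha Wald significance level (default 0.05).
#' @param ... further arguments to [fit_stage2()] for the final fit.
#' @return list `ledger` (audit data frame), `final_ti`, `final_tv`,
#'   `fit` (final `"stage2_fit"`), `metrics` (final harness metrics).
#' @export
select_covariates <- function(base_ti, candidates_ti, harness, u_hat, X,
                              base_tv = character(0), tv_harness = NULL,
                              expected_sign = NULL, threshold = 0.002,
                              alpha = 0.05, ...) {
  ledger <- list()
  log_row <- function(phase, terms, metric, decision, reason) {
    ledger[[length(ledger) + 1]] <<- data.frame(
      phase = phase, terms = paste(terms, collapse = "+"),
      metric = metric, decision = decision, reason = reason,
      stringsAsFactors = FALSE
    )
  }

  # phase 1: time-varying drop phase (monthly CV R2)
  tv_keep <- base_tv
  if (length(base_tv) > 0 && !is.null(tv_harness)) {
    full_m <- tv_harness(base_tv)$monthly_r2
    log_row("tv_base", base_tv, full_m, "start", "")
    for (p in base_tv) {
      m_wo <- tv_harness(setdiff(tv_keep, p))$monthly_r2
      if (m_wo >= full_m - threshold) {
        tv_keep <- setdiff(tv_keep, p)
        log_row("tv_drop", p, m_wo, "dropped",
          "no monthly CV R2 improvement")
        full_m <- m_wo
      } else {
        log_row("tv_drop", p, m_wo, "kept", "improves monthly CV R2")
      }
    }
  } else if (length(base_tv) > 0) {
    log_row("tv_drop", base_tv, NA, "skipped", "no tv harness configured")
  }

  # phase 2: greedy forward addition of time-invariant candidates by
  # spatial CV R2
  cur <- base_ti
  cur_metric <- harness(cur)$spatial_r2
  log_row("ti_base", cur, cur_metric, "start", "")
  pool <- candidates_ti
  # rank screen: candidates collinear with current terms are removed
  for (cand in candidates_ti) {
    if (cand %in% cur) next
    Xc <- cbind(1, as.matrix(X[, cur, drop = FALSE]), X[[cand]])
    if (qr(Xc)$rank < ncol(Xc)) {
      pool <- setdiff(pool, cand)
      log_row("ti_rank", cand, NA, "dropped", "collinear with model terms")
    }
  }
  repeat {
    if (length(pool) == 0) break
    scores <- vapply(pool, function(cand) {
      harness(union(cur, cand))$spatial_r2
    }, numeric(1))
    best <- names(scores)[which.max(scores)]
    if (max(scores) > cur_metric + threshold) {
      cur <- union(cur, best)
      cur_metric <- max(scores)
      pool <- setdiff(pool, best)
      log_row("ti_add", best, cur_metric, "added",
        "highest spatial CV R2")
    } else {
      for (cand in pool) {
        log_row("ti_add", cand, scores[[cand]], "rejected",
          "no spatial CV R2 improvement")
      }
      break
    }
  }

  # phase 3: Wald significance screen on the full-data fit
  fit <- fit_stage2(u_hat, X, covariates = cur, ...)
  repeat {
    p_vals <- fit$wald_p[cur]
    worst <- names(p_vals)[which.max(p_vals)]
    if (length(p_vals) == 0 || max(p_vals) <= alpha) break
    cur <- setdiff(cur, worst)
    log_row("wald", worst, max(p_vals), "dropped",
      sprintf("Wald p > %.2f", alpha))
    if (length(cur) == 0) break
    fit <- fit_stage2(u_hat, X, covariates = cur, ...)
  }

  # phase 4: a-priori sign screen on the fitted smooth's net trend
  if (!is.null(expected_sign)) {
    for (q in intersect(cur, names(expected_sign))) {
      v <- X[[q]]
      qs <- stats::quantile(v, c(0.2, 0.8))
      fq <- predict(fit$fit, smooth_values = stats::setNames(list(v), q))
      trend <- mean(fq[v >= qs[2]]) - mean(fq[v <= qs[1]])
      if (sign(trend) != 0 && sign(trend) != expected_sign[[q]]) {
        cur <- setdiff(cur, q)
        log_row("sign", q, trend, "dropped", "sign")
      }
    }
    if (length(setdiff(names(fit$wald_p), c(cur, fit$inter_labels))) > 0 ||
      !setequal(intersect(cur, fit$covariates), fit$covariates)) {
      fit <- if (length(cur) > 0) {
        fit_stage2(u_hat, X, covariates = cur, ...)
      } else {
        fit
      }
    }
  }
  if (length(cur) == 0) {
    warning("empty final model; falling back to intercept + spatial term")
    fit <- fit_stage2(u_hat, X, covariates = character(0), ...)
  }
  final_metric <- harness(cur)$spatial_r2
  log_row("final", cur, final_metric, "final", "")

  list(
    ledger = do.call(rbind, ledger), final_ti = cur, final_tv = tv_keep,
    fit = fit,
    metrics = list(spatial_r2 = final_metric, base_spatial_r2 = NULL)
  )
}
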