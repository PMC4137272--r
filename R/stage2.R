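#' Stage 2: domain-wide spatial model on site intercepts
#'
#' The second stage smooths the stage-1 site intercepts over the whole
#' domain,
#' \deqn{\hat u_i = \alpha + \sum_q d_q(X_{i,q}) + g(s_i) + b_i,
#'   \quad b_i \sim N(0, \sigma^2_b)}
#' with one-dimensional penalized smooths of the time-invariant (GIS-type)
#' covariates — each limited to at most 6 effective degrees of freedom —
#' and a domain-wide thin-plate surface whose basis dimension is
#' \eqn{k = \lfloor (I - Q) \cdot 0.9 \rfloor} for \eqn{I} sites and
#' \eqn{Q} covariates.  Regional interactions of covariate effects are
#' screened with block Wald tests, and covariates are selected by
#' cross-validated predictive accuracy plus significance and a-priori sign
#' screens.
#'
#' @name pmgamm-stage2
#' @keywords internal
NULL

#' Fit the stage-2 spatial model
#'
#' @param u_hat data frame `site`, `x`, `y`, `u` (one row per site) from
#'   [extract_site_intercepts()]; an optional `region` column enables
#'   regional interactions.
#' @param X data frame of time-invariant covariates, one row per site,
#'   aligned with `u_hat` (columns named).
#' @param covariates character vector of columns of `X` to include as 1-D
#'   smooths (default: all).
#' @param interactions character vector of covariates whose effect is
#'   allowed to differ by region group; see [test_region_interaction()].
#' @param k_spatial basis dimension of the domain-wide surface; default
#'   `floor((I - Q) * 0.9)`, reduced if the design would exceed the number
#'   of sites.
#' @param df_cap edf ceiling per covariate smooth (default 6).
#' @param gamma GCV multiplier (default 1.4).
#' @param spatial_df_cap optional edf ceiling on the spatial term
#'   (default `Inf`, i.e. uncapped).
#' @return object of class `"stage2_fit"`: the penalized fit, per-term edf
#'   and Wald p-values, `sigma2_b` (residual site variance), and prediction
#'   metadata.
#' @export
fit_stage2 <- function(u_hat, X = NULL, covariates = NULL,
                       interactions = character(0), k_spatial = NULL,
                       df_cap = 6, gamma = 1.4, spatial_df_cap = Inf) {
  stopifnot(all(c("site", "x", "y", "u") %in% names(u_hat)))
  I <- nrow(u_hat)
  if (is.null(covariates)) {
    covariates <- if (is.null(X)) character(0) else colnames(X)
  }
  Q <- length(covariates)
  if (I - Q < 10) stop("too few sites relative to covariates")
  coords <- as.matrix(u_hat[, c("x", "y")])

  smooths <- list()
  k_used <- 0L
  for (q in covariates) {
    b <- build_basis_1d(X[[q]], k = 10, label = q)
    smooths[[q]] <- smooth_term(b, X[[q]], label = q)
    k_used <- k_used + b$k - 1L
  }
  # regional interaction terms: deviation smooths on indicator-masked rows
  para <- matrix(1, I, 1, dimnames = list(NULL, "(Intercept)"))
  inter_labels <- character(0)
  if (length(interactions) > 0) {
    if (is.null(u_hat$region)) stop("interactions require a 'region' column")
    reg <- factor(u_hat$region)
    if (nlevels(reg) < 2) stop("interactions require more than one region")
    Rm <- stats::model.matrix(~reg,
      contrasts.arg = list(reg = "contr.sum"))[, -1, drop = FALSE]
    colnames(Rm) <- paste0("region_c", seq_len(ncol(Rm)))
    para <- cbind(para, Rm)
    for (q in interactions) {
      grps <- levels(reg)[-nlevels(reg)] # last level is the reference
      for (g in grps) {
        lab <- paste0(q, ":", g)
        b <- build_basis_1d(X[[q]], k = 10, label = lab)
        tm <- smooth_term(b, X[[q]], label = lab)
        tm$mask <- as.numeric(reg == g)
        tm$mask_meta <- list(group = g)
        smooths[[lab]] <- tm
        inter_labels <- c(inter_labels, lab)
        k_used <- k_used + b$k - 1L
      }
    }
  }

  k_max <- I - ncol(para) - k_used - 5L
  if (is.null(k_spatial)) k_spatial <- as.integer(floor((I - Q) * 0.9))
  k_flag <- k_spatial > k_max
  k_spatial <- max(10L, min(k_spatial, k_max))
  bs <- build_basis_tprs(coords, k = k_spatial, label = "space")
  smooths[["space"]] <- smooth_term(bs, coords, label = "space")

  fit <- fit_penalized(u_hat$u, unname(smooths), para, gamma = gamma)

  # iterate the caps: raising one term's lambda frees fit that neighboring
  # terms can re-absorb, so pass until all ceilings hold together
  capped <- c(
    stats::setNames(rep(df_cap, Q + length(inter_labels)),
      c(covariates, inter_labels)),
    if (is.finite(spatial_df_cap)) c(space = spatial_df_cap)
  )
  for (pass in 1:10) {
    viol <- names(capped)[fit$edf[names(capped)] > capped + 0.1]
    if (length(viol) == 0) break
    for (lab in viol) fit <- cap_edf(fit, lab, capped[[lab]])
  }

  wald <- lapply(
    stats::setNames(nm = setdiff(names(smooths), "space")),
    function(lab) wald_smooth_test(fit, lab)
  )
  structure(
    list(
      fit = fit, covariates = covariates, interactions = interactions,
      inter_labels = inter_labels,
      region_levels = if (length(interactions)) levels(factor(u_hat$region)),
      sigma2_b = fit$scale, k_spatial = k_spatial,
      k_spatial_reduced = k_flag,
      wald_p = vapply(wald, function(w) w$p_value, numeric(1)),
      edf = fit$edf, sites = u_hat$site,
      X_ranges = if (Q > 0) {
        lapply(stats::setNames(nm = covariates), function(q) range(X[[q]]))
      }
    ),
    class = "stage2_fit"
  )
}

#' Predict the stage-2 component at new locations
#'
#' Evaluates \eqn{\alpha + \sum_q d_q(X_q) + g(s)} (plus regional terms when
#' present) with pointwise standard errors from the posterior covariance.
#'
#' @param s2 a `"stage2_fit"`.
#' @param newdata data frame with `x`, `y`, the model's covariate columns,
#'   and `region` when the fit has regional terms.
#' @return list `mean`, `se`.
#' @export
stage2_component <- function(s2, newdata) {
  stopifnot(inherits(s2, "stage2_fit"))
  n_new <- nrow(newdata)
  fit <- s2$fit
  Xn <- matrix(0, n_new, ncol(fit$X))
  para <- matrix(1, n_new, 1)
  if (length(s2$interactions) > 0) {
    reg <- factor(newdata$region, levels = s2$region_levels)
    Rm <- stats::model.matrix(~reg,
      contrasts.arg = list(reg = "contr.sum"))[, -1, drop = FALSE]
    para <- cbind(para, Rm)
  }
  para <- para[, fit$block_kept$parametric, drop = FALSE]
  Xn[, fit$blocks$parametric] <- para
  term_labels <- vapply(fit$terms, `[[`, "", "label")
  for (j in seq_along(fit$terms)) {
    tm <- fit$terms[[j]]
    lab <- term_labels[j]
    vals <- if (lab == "space") {
      as.matrix(newdata[, c("x", "y")])
    } else {
      q <- sub(":.*$", "", lab)
      newdata[[q]]
    }
    D <- basis_design(tm$basis, vals)
    if (!is.null(tm$Zc)) D <- D %*% tm$Zc
    if (!is.null(tm$mask_meta)) {
      g <- tm$mask_meta$group
      D <- D * as.numeric(as.character(newdata$region) == g)
    }
    D <- D[, fit$block_kept[[lab]], drop = FALSE]
    Xn[, fit$blocks[[lab]]] <- D
  }
  mu <- drop(Xn %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((Xn %*% fit$Vb) * Xn), 0))
  list(mean = mu, se = se)
}

#' Test a regional interaction of a covariate effect
#'
#' Expands the stage-2 model with a region main effect and region-specific
#' deviation smooths of covariate `q`, and reports a block Wald test of the
#' joint deviation (smooth deviations plus regional intercept contrasts).
#' The interaction is retained when p <= `alpha`.  Regions with fewer than
#' `min_region_sites` sites are pooled with the reference group.
#'
#' @param u_hat,X as in [fit_stage2()] (with a `region` column in `u_hat`).
#' @param covariates model covariates.
#' @param q the covariate to test.
#' @param alpha significance level (default 0.05).
#' @param min_region_sites pooling threshold (default 15).
#' @param ... passed to [fit_stage2()].
#' @return list `p_value`, `retain`, `fit` (the expanded fit when retained,
#'   otherwise the base fit), `pooled` (regions pooled into the reference).
#' @export
test_region_interaction <- function(u_hat, X, covariates, q, alpha = 0.05,
                                    min_region_sites = 15, ...) {
  if (is.null(u_hat$region)) stop("no 'region' column")
  reg <- factor(u_hat$region)
  if (nlevels(reg) < 2) stop("cannot test interactions in a single region")
  cnt <- table(reg)
  small <- names(cnt)[cnt < min_region_sites]
  pooled <- character(0)
  if (length(small) > 0) {
    warning(sprintf(
      "pooling small region(s) %s with the reference group",
      paste(small, collapse = ", ")
    ))
    pooled <- small
    big <- names(cnt)[cnt >= min_region_sites]
    ref <- big[length(big)]
    u_hat$region <- as.character(u_hat$region)
    u_hat$region[u_hat$region %in% small] <- ref
    reg <- factor(u_hat$region)
    if (nlevels(reg) < 2) stop("pooling left a single region")
  }
  ex <- fit_stage2(u_hat, X, covariates, interactions = q, ...)
  idx_all <- integer(0)
  for (lab in ex$inter_labels) {
    idx_all <- c(idx_all, ex$fit$blocks[[lab]])
  }
  # regional intercept contrasts sit after the global intercept
  par_idx <- ex$fit$blocks$parametric
  if (length(par_idx) > 1) idx_all <- c(par_idx[-1], idx_all)
  beta <- ex$fit$coefficients[idx_all]
  V <- ex$fit$Vb[idx_all, idx_all, drop = FALSE]
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  tol <- max(eg$values) * 1e-8
  pos <- eg$values > tol
  stat <- sum((crossprod(
    eg$vectors[, pos, drop = FALSE],
    beta
  ) / sqrt(eg$values[pos]))^2)
  edf_dev <- sum(ex$fit$edf[ex$inter_labels]) + length(par_idx) - 1
  df <- max(1L, as.integer(round(edf_dev)))
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  retain <- p <= alpha
  base <- if (retain) ex else fit_stage2(u_hat, X, covariates, ...)
  list(
    p_value = p, retain = retain, df = df, statistic = stat,
    fit = if (retain) ex else base, pooled = pooled
  )
}
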