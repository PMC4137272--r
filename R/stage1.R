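#' Stage 1: regional back-fitting of monthly panels
#'
#' The first modeling stage parses each region's monthly log-concentration
#' panel
#' \deqn{y_{i,t} = u_i + \alpha_{t,r} + \sum_p f_{p,r}(Z_{i,t,p}) +
#'   g_{t,r}(s_i) + e_{i,t}, \quad e_{i,t} \sim N(0, \sigma^2_{e\,r,t})}
#' into site intercepts \eqn{u_i}, mean-zero monthly regional intercepts
#' \eqn{\alpha_{t,r}}, one-dimensional penalized smooths of the time-varying
#' covariates, and per-month (or per-season) thin-plate spatial surfaces.
#' The joint block (\eqn{u + \alpha + \sum f}) and the spatial surfaces are
#' estimated alternately in a back-fitting arrangement until the fitted
#' values stabilize.  Neighboring sites within a 400 km buffer participate
#' in the regional fit to suppress boundary effects; their intercepts are
#' discarded downstream.
#'
#' @name pmgamm-stage1
#' @keywords internal
NULL

#' Stage-1 configuration
#'
#' @param gamma GCV multiplier for the joint covariate step (default 1.4).
#' @param gamma_spatial GCV multiplier for the spatial surfaces (1.4; use
#'   1.8 for data-sparse regions).
#' @param tol back-fitting convergence tolerance: maximum absolute change in
#'   fitted values on the log scale (default 1e-4).
#' @param max_iter maximum back-fitting sweeps (default 20).
#' @param k_z basis dimension for 1-D covariate smooths (default 10).
#' @param k_factor spatial basis dimension as a fraction of the site count
#'   (default 0.9).
#' @param reselect_sweeps number of sweeps during which smoothing parameters
#'   are re-selected by GCV before being frozen (default 3).
#' @param min_month_sites months with fewer sites contribute a zero spatial
#'   surface (default 5).
#' @param h_term include a 1-D smooth of the month index in the joint step
#'   (the temporal trend of the ratio model).
#' @param month_intercepts include mean-zero monthly regional intercepts in
#'   the joint step (default `TRUE`; the ratio model replaces them with the
#'   temporal smooth, so set `FALSE` when `h_term` is on).
#' @param seasonal fit spatial surfaces by season (4 per region) instead of
#'   by month.
#' @param lambda_z optional named vector of fixed smoothing parameters for
#'   the covariate smooths (bypasses GCV; used for oracle comparisons).
#' @param lambda_g optional fixed smoothing parameter for all spatial
#'   surfaces.
#' @return list of class `"stage1_config"`.
#' @export
stage1_config <- function(gamma = 1.4, gamma_spatial = 1.4, tol = 1e-4,
                          max_iter = 20, k_z = 10, k_factor = 0.9,
                          reselect_sweeps = 3, min_month_sites = 5,
                          h_term = FALSE, seasonal = FALSE,
                          month_intercepts = TRUE,
                          lambda_z = NULL, lambda_g = NULL) {
  structure(as.list(environment()), class = "stage1_config")
}

#' Month-to-season mapping
#'
#' Meteorological seasons: winter = Dec-Feb, spring = Mar-May, summer =
#' Jun-Aug, autumn = Sep-Nov.  Month indices are interpreted cyclically
#' (index 1 = January).
#'
#' @param month integer month index (1-based).
#' @return factor with levels winter, spring, summer, autumn.
#' @export
month_season <- function(month) {
  cal <- ((month - 1) %% 12) + 1
  s <- c(
    "winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter"
  )[cal]
  factor(s, levels = c("winter", "spring", "summer", "autumn"))
}

#' Attach buffer sites to regional fitting sets
#'
#' Each region's fitting set is its own sites plus out-of-region sites
#' within `buffer_km` of the region's rectangular boundary; buffer sites are
#' flagged so their intercepts can be discarded after fitting.
#'
#' @param sites data frame with `site`, `x`, `y`, `region` (coordinates in
#'   km).
#' @param geometry data frame with `region`, `xmin`, `xmax`, `ymin`,
#'   `ymax` describing each region's rectangle.
#' @param buffer_km buffer distance (default 400).
#' @return named list (one element per region) of site data frames with a
#'   logical `buffer` column; with `buffer_km = 0` the sets partition the
#'   sites.
#' @export
attach_buffer <- function(sites, geometry, buffer_km = 400) {
  stopifnot(all(c("site", "x", "y", "region") %in% names(sites)))
  out <- list()
  for (i in seq_len(nrow(geometry))) {
    r <- geometry$region[i]
    dx <- pmax(geometry$xmin[i] - sites$x, sites$x - geometry$xmax[i], 0)
    dy <- pmax(geometry$ymin[i] - sites$y, sites$y - geometry$ymax[i], 0)
    dist <- sqrt(dx^2 + dy^2)
    inside <- sites$region == r
    take <- inside | dist <= buffer_km
    if (!any(inside)) stop(sprintf("region '%s' has no sites", r))
    s <- sites[take, , drop = FALSE]
    s$buffer <- !inside[take]
    out[[as.character(r)]] <- s
  }
  out
}

#' Back-fit one region's monthly panel
#'
#' @param panel data frame with columns `site`, `x`, `y` (coordinates),
#'   `month`, `value` (the log-scale response) plus one column per
#'   time-varying covariate; an
#'   optional logical `buffer` column marks buffer-zone observations.
#' @param z_vars character vector of time-varying covariate column names
#'   (may be empty).
#' @param config a [stage1_config()].
#' @param region region label carried into the result.
#' @return `"stage1_fit"`: site intercepts `u` (with buffer flags), monthly
#'   intercepts `alpha` (mean zero across months), covariate smooths, the
#'   per-group spatial surface fits, per-month residual variances
#'   `sigma2_e`, and the convergence trace.
#' @export
backfit_region <- function(panel, z_vars = character(0),
                           config = stage1_config(), region = NA) {
  stopifnot(all(c("site", "x", "y", "month", "value") %in% names(panel)))
  stopifnot(all(z_vars %in% names(panel)))
  if (length(unique(panel$month)) < 2) stop("panel needs at least 2 months")
  if (length(unique(panel$site)) < 10) stop("panel needs at least 10 sites")
  panel <- panel[order(panel$site, panel$month), , drop = FALSE]
  n <- nrow(panel)
  site_f <- factor(panel$site)
  month_levels <- sort(unique(panel$month))
  month_f <- factor(panel$month, levels = month_levels)
  n_months <- length(month_levels)

  # parametric block: site indicators (carry the mean) + mean-zero monthly
  # intercepts via sum contrasts
  S_mat <- stats::model.matrix(~ 0 + site_f)
  colnames(S_mat) <- paste0("site:", levels(site_f))
  if (isTRUE(config$month_intercepts)) {
    M_mat <- stats::model.matrix(
      ~month_f,
      contrasts.arg = list(month_f = "contr.sum")
    )[, -1, drop = FALSE]
    colnames(M_mat) <- paste0("mon_c", seq_len(ncol(M_mat)))
  } else {
    M_mat <- matrix(0, n, 0)
  }
  P <- cbind(S_mat, M_mat)

  smooth_specs <- list()
  for (zv in z_vars) {
    b <- build_basis_1d(panel[[zv]], k = config$k_z, label = zv)
    lam <- if (!is.null(config$lambda_z)) config$lambda_z[[zv]] else NULL
    smooth_specs[[zv]] <- list(basis = b, values = panel[[zv]], lambda = lam)
  }
  if (isTRUE(config$h_term)) {
    mi <- as.numeric(panel$month)
    b <- build_basis_1d(mi, k = min(config$k_z, length(month_levels)),
      label = "h_month")
    smooth_specs[["h_month"]] <- list(
      basis = b, values = mi,
      lambda = if (!is.null(config$lambda_z)) {
        config$lambda_z[["h_month"]]
      } else {
        NULL
      }
    )
  }

  group_f <- if (isTRUE(config$seasonal)) {
    month_season(as.numeric(as.character(month_f)))
  } else {
    month_f
  }
  groups <- levels(droplevels(group_f))
  group_rows <- lapply(groups, function(g) which(group_f == g))
  names(group_rows) <- groups
  coords <- as.matrix(panel[, c("x", "y")])

  # one spatial basis per group, reused across sweeps
  g_basis <- list()
  for (g in groups) {
    idx <- group_rows[[g]]
    pts <- unique(coords[idx, , drop = FALSE])
    n_sites_g <- length(unique(panel$site[idx]))
    if (n_sites_g < config$min_month_sites || nrow(pts) < 4) {
      g_basis[[g]] <- NULL
      next
    }
    k_g <- max(4L, min(
      as.integer(floor(n_sites_g * config$k_factor)),
      nrow(pts), length(idx) - 2L
    ))
    g_basis[[g]] <- build_basis_tprs(pts, k = k_g, label = "space")
  }

  y <- panel$value
  x_cur <- numeric(n) # current spatial contribution
  total_prev <- numeric(n)
  trace <- numeric(0)
  joint <- NULL
  g_fits <- stats::setNames(vector("list", length(groups)), groups)
  lambda_z_cur <- NULL
  lambda_g_cur <- stats::setNames(rep(NA_real_, length(groups)), groups)
  converged <- FALSE

  run_sweep <- function(x_in, reselect) {
    terms <- lapply(names(smooth_specs), function(nm) {
      sp <- smooth_specs[[nm]]
      lam <- sp$lambda
      if (is.null(lam) && !reselect) lam <- lambda_z_cur[[nm]]
      smooth_term(sp$basis, sp$values, label = nm, lambda = lam)
    })
    joint <<- fit_penalized(y - x_in,
      smooths = terms, parametric = P,
      gamma = config$gamma
    )
    lambda_z_cur <<- as.list(joint$lambda)
    r2 <- y - joint$fitted
    Tx <- numeric(n)
    for (g in groups) {
      if (is.null(g_basis[[g]])) next
      idx <- group_rows[[g]]
      lam <- config$lambda_g
      if (is.null(lam) && !reselect && is.finite(lambda_g_cur[[g]])) {
        lam <- lambda_g_cur[[g]]
      }
      gf <- fit_penalized(r2[idx],
        smooths = list(smooth_term(g_basis[[g]], coords[idx, , drop = FALSE],
          label = "space", lambda = lam
        )),
        gamma = config$gamma_spatial
      )
      lambda_g_cur[[g]] <<- gf$lambda[["space"]]
      g_fits[[g]] <<- gf
      b0 <- gf$coefficients[gf$blocks$parametric]
      Tx[idx] <- gf$fitted - b0
    }
    Tx
  }

  any_free <- is.null(config$lambda_g) || any(vapply(
    smooth_specs, function(s) is.null(s$lambda), TRUE
  ))
  n_select <- if (any_free) min(config$reselect_sweeps, config$max_iter) else 1L

  it <- 0
  for (s in seq_len(n_select)) {
    it <- it + 1
    Tx <- run_sweep(x_cur, reselect = any_free)
    total <- joint$fitted + Tx
    delta <- max(abs(total - total_prev))
    trace <- c(trace, delta)
    total_prev <- total
    x_cur <- Tx
    if (it > 1 && delta < config$tol) {
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    # Smoothing parameters are now frozen, so one back-fitting sweep is the
    # affine map T(x) = c + M x with M built from the cached hat operators;
    # solve the fixed point (I - M) x = c by GMRES, warm-started at the
    # current iterate, then verify with plain sweeps.
    joint_hat <- function(v) penfit_hat_apply(joint, v)
    spatial_hat <- function(v) {
      out <- numeric(n)
      for (g in groups) {
        if (is.null(g_fits[[g]])) next
        idx <- group_rows[[g]]
        gf <- g_fits[[g]]
        b <- backsolve(gf$cholA, forwardsolve(
          t(gf$cholA), crossprod(gf$X, v[idx])
        ))
        out[idx] <- drop(gf$X %*% b) - b[gf$blocks$parametric[1]]
      }
      out
    }
    mat_vec <- function(v) v - spatial_hat(joint_hat(v)) # (I - M) v
    c_vec <- spatial_hat(y - joint_hat(y))
    x_cur <- gmres_solve(mat_vec, c_vec,
      x0 = x_cur,
      rtol = min(1e-11, config$tol * 1e-4), max_iter = min(n, 200)
    )
    # plain sweeps from the solution: records the convergence check
    for (s in seq_len(max(config$max_iter - it, 2))) {
      it <- it + 1
      Tx <- run_sweep(x_cur, reselect = FALSE)
      total <- joint$fitted + Tx
      delta <- max(abs(total - total_prev))
      trace <- c(trace, delta)
      total_prev <- total
      x_cur <- Tx
      if (delta < config$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning(sprintf(
      "back-fitting did not reach tol %.1e in %d sweeps (last delta %.2e)",
      config$tol, config$max_iter, trace[length(trace)]
    ))
  }

  resid <- y - total_prev
  # residual variance per region-month, with an edf-proportional correction
  sigma2_e <- vapply(seq_along(month_levels), function(ti) {
    idx <- which(month_f == month_levels[ti])
    n_t <- length(idx)
    g <- if (isTRUE(config$seasonal)) {
      as.character(month_season(as.numeric(as.character(month_levels[ti]))))
    } else {
      as.character(month_levels[ti])
    }
    edf_g <- if (!is.null(g_fits[[g]])) {
      g_fits[[g]]$edf_total * n_t / length(group_rows[[g]])
    } else {
      0
    }
    edf_t <- joint$edf_total * n_t / n + edf_g
    sum(resid[idx]^2) / max(n_t - edf_t, 1)
  }, numeric(1))
  names(sigma2_e) <- as.character(month_levels)

  site_tab <- panel[!duplicated(panel$site), c("site", "x", "y")]
  if ("buffer" %in% names(panel)) {
    site_tab$buffer <- panel$buffer[!duplicated(panel$site)]
  } else {
    site_tab$buffer <- FALSE
  }
  u_idx <- match(paste0("site:", site_tab$site),
    colnames(P)[joint$blocks$parametric])
  site_tab$u <- joint$coefficients[joint$blocks$parametric][u_idx]

  if (ncol(M_mat) > 0) {
    mc <- joint$coefficients[joint$blocks$parametric][
      seq(ncol(S_mat) + 1, length.out = ncol(M_mat))
    ]
    alpha <- c(mc, -sum(mc))
  } else {
    alpha <- rep(0, n_months)
  }
  names(alpha) <- as.character(month_levels)

  structure(
    list(
      region = region, config = config, z_vars = z_vars,
      joint = joint, g_fits = g_fits, g_basis = g_basis,
      group_rows_n = vapply(group_rows, length, 0L),
      seasonal = isTRUE(config$seasonal),
      month_levels = month_levels,
      n_site_cols = ncol(S_mat), n_month_cols = ncol(M_mat),
      sites = site_tab, alpha = alpha, sigma2_e = sigma2_e,
      fitted = total_prev, residuals = resid,
      trace = trace, converged = converged
    ),
    class = "stage1_fit"
  )
}

#' Extract site intercepts from a stage-1 fit
#'
#' Returns the estimated site-specific intercepts \eqn{\hat u_i} for
#' in-region sites only; intercepts of 400 km-buffer sites are discarded
#' (their information enters the neighboring region's own fit).
#'
#' @param fit a `"stage1_fit"`.
#' @return data frame `site`, `x`, `y`, `u`.
#' @export
extract_site_intercepts <- function(fit) {
  stopifnot(inherits(fit, "stage1_fit"))
  s <- fit$sites[!fit$sites$buffer, c("site", "x", "y", "u")]
  rownames(s) <- NULL
  s
}

#' Evaluate stage-1 components at new site-months
#'
#' Computes \eqn{\alpha_{t,r} + \sum_p f_{p,r}(Z_p) + g_{t,r}(s)} (plus the
#' temporal smooth when present) with the associated variance contributions
#' from the monthly intercept and the spatial surface.
#'
#' @param fit a `"stage1_fit"`.
#' @param newdata data frame with `x`, `y`, `month` and the fit's
#'   time-varying covariate columns.
#' @return list `mean`, `var` (monthly-intercept + surface variance) and
#'   `sigma2_e` (per-row residual variance for observation-level intervals).
#' @export
stage1_component <- function(fit, newdata) {
  stopifnot(inherits(fit, "stage1_fit"))
  n_new <- nrow(newdata)
  month_chr <- as.character(newdata$month)
  if (!all(month_chr %in% as.character(fit$month_levels))) {
    stop("month outside the stage-1 training window")
  }
  mu <- fit$alpha[month_chr]
  # monthly-intercept variance from the joint fit's contrast block
  var_alpha <- numeric(n_new)
  if (fit$n_month_cols > 0) {
    Vb <- fit$joint$Vb
    kept_par <- fit$joint$blocks$parametric
    mstart <- fit$n_site_cols
    mcols <- kept_par[seq(mstart + 1, length.out = fit$n_month_cols)]
    Vm <- Vb[mcols, mcols, drop = FALSE]
    lev <- as.character(fit$month_levels)
    Cm <- matrix(0, n_new, fit$n_month_cols)
    ti <- match(month_chr, lev)
    last <- length(lev)
    for (i in seq_len(n_new)) {
      if (ti[i] < last) Cm[i, ti[i]] <- 1 else Cm[i, ] <- -1
    }
    var_alpha <- rowSums((Cm %*% Vm) * Cm)
  }

  smooth_mu <- numeric(n_new)
  for (zv in fit$z_vars) {
    smooth_mu <- smooth_mu + predict(fit$joint,
      smooth_values = stats::setNames(list(newdata[[zv]]), zv)
    )
  }
  if ("h_month" %in% names(fit$joint$lambda)) {
    smooth_mu <- smooth_mu + predict(fit$joint,
      smooth_values = list(h_month = as.numeric(newdata$month))
    )
  }

  g_mu <- numeric(n_new)
  g_var <- numeric(n_new)
  grp <- if (fit$seasonal) {
    as.character(month_season(as.numeric(newdata$month)))
  } else {
    month_chr
  }
  for (g in unique(grp)) {
    idx <- which(grp == g)
    gf <- fit$g_fits[[g]]
    if (is.null(gf)) next
    pr <- predict(gf,
      smooth_values = list(space = as.matrix(newdata[idx, c("x", "y")])),
      se_fit = TRUE
    )
    g_mu[idx] <- pr$fit
    g_var[idx] <- pr$se^2
  }
  sig_e <- fit$sigma2_e[month_chr]
  list(
    mean = unname(mu + smooth_mu + g_mu),
    var = unname(var_alpha + g_var),
    sigma2_e = unname(sig_e)
  )
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf(
    "Stage-1 fit, region %s: %d sites (%d buffer), %d months, %s\n",
    x$region, nrow(x$sites), sum(x$sites$buffer),
    length(x$month_levels),
    if (x$converged) {
      sprintf("converged in %d sweeps", length(x$trace))
    } else {
      "NOT converged"
    }
  ))
  invisible(x)
}
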