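#' Penalized least-squares fitting with GCV smoothing-parameter selection
#'
#' The single fitting routine behind every smooth in the package.  A model is
#' a parametric block (intercepts, site/month indicators, region factors)
#' plus any number of penalized smooth terms; smoothing parameters are chosen
#' by generalized cross-validation with an over-fit-guard multiplier
#' \eqn{\gamma} in the denominator: \eqn{GCV(\lambda) = n\,RSS / (n -
#' \gamma\,edf)^2}.  The multiplier (1.4 for most fits, 1.8 for sparse
#' regions) inflates the cost of effective degrees of freedom and so deters
#' over-fitting.
#'
#' @name pmgamm-penfit
#' @keywords internal
NULL

#' Define a smooth term for [fit_penalized()]
#'
#' @param basis a basis from [build_basis_1d()] or [build_basis_tprs()].
#' @param values covariate values (1-D) or coordinate matrix (TPRS) at the
#'   observations.
#' @param label term label; defaults to the basis label.
#' @param lambda fixed smoothing parameter, or `NULL` to select by GCV.
#' @param center logical; absorb a sum-to-zero-over-training constraint so
#'   the term carries no constant (default `TRUE`; the constant belongs to
#'   the parametric block).
#' @return a `"smooth_term"` specification.
#' @export
smooth_term <- function(basis, values, label = basis$label, lambda = NULL,
                        center = TRUE) {
  stopifnot(inherits(basis, "basis_1d") || inherits(basis, "basis_tprs"))
  structure(
    list(
      basis = basis, values = values, label = label,
      lambda = lambda, center = center
    ),
    class = "smooth_term"
  )
}

lambda_grid_default <- function() 10^seq(-6, 6, length.out = 41)

# Build the design block, absorbed constraint and penalty for one term.
# A term may carry a 0/1 row `mask` (region-specific deviation smooths):
# masked-out rows contribute zero design and centering is over masked-in
# rows only.
prepare_term <- function(term) {
  X <- basis_design(term$basis, term$values)
  if (!is.null(term$mask)) X <- X * term$mask
  S <- term$basis$penalty
  null_dim <- term$basis$null_dim
  Zc <- NULL
  if (isTRUE(term$center)) {
    C <- colSums(X)
    qc <- qr(matrix(C, ncol = 1))
    Zc <- qr.Q(qc, complete = TRUE)[, -1, drop = FALSE]
    X <- X %*% Zc
    S <- crossprod(Zc, S %*% Zc)
    S <- (S + t(S)) / 2
    null_dim <- null_dim - 1L
  }
  # normalize the penalty scale so smoothing parameters are comparable
  # across terms and the lambda grid stays well-conditioned
  snorm <- mean(abs(diag(S)))
  if (snorm > 0) S <- S / snorm
  list(
    X = X, S = S, Zc = Zc, null_dim = null_dim, penalty_scale = snorm,
    label = term$label, basis = term$basis, lambda = term$lambda,
    center = isTRUE(term$center), mask_meta = term$mask_meta,
    values = term$values
  )
}

# Solve the penalized normal equations for a given lambda vector and return
# the quantities every caller needs.  XtWX/XtWy/ytWy are precomputed.
penfit_solve <- function(XtWX, XtWy, ytWy, n, pen_list, blocks, lambdas,
                         gamma) {
  A <- XtWX
  for (j in seq_along(pen_list)) {
    idx <- blocks[[pen_list[[j]]$block]]
    A[idx, idx] <- A[idx, idx] + lambdas[j] * pen_list[[j]]$S
  }
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    A <- A + diag(1e-8 * mean(diag(A)), nrow(A))
    R <- chol(A)
  }
  beta <- backsolve(R, forwardsolve(t(R), XtWy))
  H <- backsolve(R, forwardsolve(t(R), XtWX)) # A^{-1} X'WX
  edf_i <- diag(H)
  rss <- max(ytWy - 2 * sum(beta * XtWy) + sum(beta * (XtWX %*% beta)), 0)
  edf <- sum(edf_i)
  denom <- n - gamma * edf
  gcv <- if (denom <= 0) Inf else n * rss / denom^2
  list(
    beta = beta, edf_i = edf_i, edf = edf, rss = rss, gcv = gcv,
    chol = R
  )
}

#' Fit a penalized additive model
#'
#' Penalized least squares over a parametric block plus smooth terms, with
#' per-term smoothing parameters chosen to minimize the gamma-inflated GCV
#' criterion over a log-spaced grid with golden-section refinement
#' (coordinate-wise cycling for multi-term models).
#'
#' @param y numeric response vector.
#' @param smooths list of [smooth_term()] specifications (may be empty).
#' @param parametric numeric matrix of unpenalized columns, or `NULL` for an
#'   intercept-only block.  Column names are preserved.
#' @param gamma GCV over-fit-guard multiplier (>= 1); 1.4 is the package-wide
#'   default for spatial and covariate smooths, 1.8 for data-sparse regions.
#' @param weights optional nonnegative observation weights.
#' @param sweeps number of coordinate-descent sweeps over the terms when more
#'   than one smoothing parameter is free (default 2).
#' @param lambda_grid candidate smoothing-parameter grid.
#' @return An object of class `"penfit"`: coefficients, per-term smoothing
#'   parameters and effective degrees of freedom, fitted values, scale
#'   estimate \eqn{\hat\sigma^2 = RSS/(n - edf)}, Bayesian posterior
#'   covariance \eqn{\hat\sigma^2 (X'WX + \sum_j \lambda_j S_j)^{-1}}, and
#'   the GCV score.
#' @export
fit_penalized <- function(y, smooths = list(), parametric = NULL,
                          gamma = 1, weights = NULL, sweeps = 2,
                          lambda_grid = lambda_grid_default()) {
  if (!all(is.finite(y))) stop("non-finite values in response 'y'")
  n <- length(y)
  if (gamma < 1) stop("'gamma' must be >= 1")
  if (is.null(parametric)) {
    parametric <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  parametric <- as.matrix(parametric)
  if (ncol(parametric) > 0 && is.null(colnames(parametric))) {
    colnames(parametric) <- paste0("para", seq_len(ncol(parametric)))
  }
  prepped <- lapply(smooths, prepare_term)
  labels <- vapply(prepped, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate smooth term labels")

  X <- parametric
  blocks <- list(parametric = seq_len(ncol(parametric)))
  for (p in prepped) {
    idx <- ncol(X) + seq_len(ncol(p$X))
    X <- cbind(X, p$X)
    blocks[[p$label]] <- idx
  }
  if (ncol(X) > n) {
    stop(sprintf(
      "design has %d columns for %d observations; reduce basis dimensions",
      ncol(X), n
    ))
  }
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(w < 0)) stop("negative weights")
  sw <- sqrt(w)
  Xw <- X * sw
  # drop linearly dependent columns (rank screen on the weighted design)
  qrX <- qr(Xw, tol = 1e-9)
  block_kept <- lapply(blocks, function(idx) seq_along(idx))
  if (qrX$rank < ncol(Xw)) {
    dropped <- sort(qrX$pivot[(qrX$rank + 1):ncol(Xw)])
    warning(sprintf(
      "dropping %d linearly dependent design column(s)", length(dropped)
    ))
    keep <- setdiff(seq_len(ncol(X)), dropped)
    remap <- match(seq_len(ncol(X)), keep)
    X <- X[, keep, drop = FALSE]
    Xw <- Xw[, keep, drop = FALSE]
    for (bn in names(blocks)) {
      kept_rel <- which(!is.na(remap[blocks[[bn]]]))
      block_kept[[bn]] <- kept_rel
      blocks[[bn]] <- remap[blocks[[bn]]][kept_rel]
    }
  }
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(Xw, y * sw)
  ytWy <- sum(w * y^2)

  pen_list <- lapply(prepped, function(p) {
    kept_rel <- block_kept[[p$label]]
    S <- p$S[kept_rel, kept_rel, drop = FALSE]
    # balance the penalty against the design block so the lambda grid
    # covers the transition from interpolation to the null-space limit
    idx <- blocks[[p$label]]
    if (length(idx) == 0) {
      return(list(block = p$label, S = matrix(0, 0, 0)))
    }
    dscale <- mean(diag(XtWX[idx, idx, drop = FALSE]))
    sscale <- mean(diag(S))
    if (is.finite(dscale) && is.finite(sscale) &&
      sscale > 0 && dscale > 0) {
      S <- S * (dscale / sscale)
    }
    list(block = p$label, S = S)
  })

  free <- which(vapply(prepped, function(p) is.null(p$lambda), TRUE))
  # free parameters start heavily smoothed so the initial total edf is small
  # and the GCV denominator is valid even for near-saturated bases
  lambdas <- vapply(prepped, function(p) {
    if (is.null(p$lambda)) 1e4 else p$lambda
  }, numeric(1))

  eval_gcv <- function(lam) {
    penfit_solve(XtWX, XtWy, ytWy, n, pen_list, blocks, lam, gamma)$gcv
  }
  if (length(free) > 0) {
    n_sweeps <- if (length(free) == 1) 1 else sweeps
    for (s in seq_len(n_sweeps)) {
      for (j in free) {
        scores <- vapply(lambda_grid, function(l) {
          lam <- lambdas
          lam[j] <- l
          eval_gcv(lam)
        }, numeric(1))
        if (!any(is.finite(scores))) {
          lambdas[j] <- lambda_grid[length(lambda_grid)]
          next
        }
        # ties (e.g. a perfect fit at every lambda) resolve to the
        # smoothest candidate
        bs <- min(scores)
        best <- max(which(scores <= bs + max(1e-12, abs(bs) * 1e-9)))
        lo <- lambda_grid[max(1, best - 1)]
        hi <- lambda_grid[min(length(lambda_grid), best + 1)]
        opt <- stats::optimize(function(ll) {
          lam <- lambdas
          lam[j] <- 10^ll
          eval_gcv(lam)
        }, lower = log10(lo), upper = log10(hi), tol = 0.05)
        cand <- 10^opt$minimum
        lambdas[j] <- if (opt$objective <= scores[best]) cand else
          lambda_grid[best]
      }
    }
  }

  sol <- penfit_solve(XtWX, XtWy, ytWy, n, pen_list, blocks, lambdas, gamma)
  fitted <- drop(X %*% sol$beta)
  scale <- sol$rss / max(n - sol$edf, 1)
  Ainv <- chol2inv(sol$chol)
  Vb <- scale * Ainv
  term_edf <- vapply(names(blocks), function(bn) {
    sum(sol$edf_i[blocks[[bn]]])
  }, numeric(1))
  names(lambdas) <- labels
  structure(
    list(
      coefficients = drop(sol$beta),
      blocks = blocks,
      terms = prepped,
      lambda = lambdas,
      edf = term_edf,
      edf_total = sol$edf,
      fitted = fitted,
      residuals = y - fitted,
      rss = sol$rss,
      scale = scale,
      Vb = Vb,
      gcv = sol$gcv,
      gamma = gamma,
      y = y, X = X, weights = w, n = n,
      XtWX = XtWX, XtWy = XtWy, ytWy = ytWy, pen_list = pen_list,
      block_kept = block_kept, cholA = sol$chol,
      parametric_names = colnames(parametric)
    ),
    class = "penfit"
  )
}

# refit an existing penfit at new lambdas (no reselection)
penfit_refit <- function(fit, lambdas) {
  sol <- penfit_solve(
    fit$XtWX, fit$XtWy, fit$ytWy, fit$n, fit$pen_list, fit$blocks,
    lambdas, fit$gamma
  )
  fitted <- drop(fit$X %*% sol$beta)
  scale <- sol$rss / max(fit$n - sol$edf, 1)
  Vb <- scale * chol2inv(sol$chol)
  term_edf <- vapply(names(fit$blocks), function(bn) {
    sum(sol$edf_i[fit$blocks[[bn]]])
  }, numeric(1))
  out <- fit
  out$coefficients <- drop(sol$beta)
  out$lambda <- stats::setNames(lambdas, names(fit$lambda))
  out$edf <- term_edf
  out$edf_total <- sol$edf
  out$fitted <- fitted
  out$residuals <- fit$y - fitted
  out$rss <- sol$rss
  out$scale <- scale
  out$Vb <- Vb
  out$gcv <- sol$gcv
  out$cholA <- sol$chol
  out
}

# full-memory GMRES for (I - M) x = c given only matrix-vector products;
# used to solve the back-fitting fixed point once smoothing parameters are
# frozen (the sweep map is then affine)
gmres_solve <- function(mat_vec, b, x0 = NULL, rtol = 1e-10,
                        max_iter = 100) {
  n <- length(b)
  if (is.null(x0)) x0 <- numeric(n)
  r0 <- b - mat_vec(x0)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(x0)
  }
  beta <- sqrt(sum(r0^2))
  if (beta <= rtol * bnorm) {
    return(x0)
  }
  m <- min(max_iter, n)
  V <- matrix(0, n, m + 1)
  H <- matrix(0, m + 1, m)
  V[, 1] <- r0 / beta
  j_used <- m
  for (j in seq_len(m)) {
    w <- mat_vec(V[, j])
    for (i in seq_len(j)) {
      H[i, j] <- sum(w * V[, i])
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1, j] <- sqrt(sum(w^2))
    e1 <- c(beta, numeric(j))
    yj <- qr.solve(H[seq_len(j + 1), seq_len(j), drop = FALSE], e1)
    res <- sqrt(sum((e1 - H[seq_len(j + 1), seq_len(j), drop = FALSE] %*%
      yj)^2))
    if (res <= rtol * bnorm || H[j + 1, j] < 1e-14) {
      j_used <- j
      break
    }
    V[, j + 1] <- w / H[j + 1, j]
    j_used <- j
  }
  e1 <- c(beta, numeric(j_used))
  yj <- qr.solve(H[seq_len(j_used + 1), seq_len(j_used), drop = FALSE], e1)
  drop(x0 + V[, seq_len(j_used), drop = FALSE] %*% yj)
}

# apply the hat (influence) operator of a fitted penfit to a new response
penfit_hat_apply <- function(fit, v) {
  b <- backsolve(fit$cholA, forwardsolve(
    t(fit$cholA), crossprod(fit$X, v * fit$weights)
  ))
  drop(fit$X %*% b)
}

#' Cap the effective degrees of freedom of a smooth term
#'
#' If the GCV-selected edf of `term` exceeds `max_df`, the term's smoothing
#' parameter is increased by monotone bisection on \eqn{\log\lambda} until
#' the edf falls to `max_df` (within 0.05); otherwise the fit is returned
#' unchanged.  Mirrors constraining a spline term to at most a fixed number
#' of degrees of freedom via its smoothing parameter.
#'
#' @param fit a `"penfit"` object.
#' @param term smooth term label.
#' @param max_df edf ceiling; must be at least the term's (post-constraint)
#'   null-space dimension.
#' @return a `"penfit"` with the possibly increased smoothing parameter.
#' @export
cap_edf <- function(fit, term, max_df) {
  stopifnot(inherits(fit, "penfit"))
  j <- match(term, names(fit$lambda))
  if (is.na(j)) stop(sprintf("no smooth term '%s' in fit", term))
  nd <- fit$terms[[j]]$null_dim
  if (max_df < nd) {
    stop(sprintf(
      "cap %.2f is below the term's null-space dimension %d", max_df, nd
    ))
  }
  if (fit$edf[[term]] <= max_df + 1e-8) {
    return(fit)
  }
  edf_at <- function(loglam) {
    lam <- fit$lambda
    lam[j] <- 10^loglam
    sol <- penfit_solve(
      fit$XtWX, fit$XtWy, fit$ytWy, fit$n, fit$pen_list, fit$blocks,
      lam, fit$gamma
    )
    sum(sol$edf_i[fit$blocks[[term]]])
  }
  lo <- log10(max(fit$lambda[j], 1e-8))
  hi <- 12
  if (edf_at(hi) > max_df) {
    warning("edf cap unattainable even at extreme smoothing; using maximum")
  } else {
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (edf_at(mid) > max_df) lo <- mid else hi <- mid
      if (hi - lo < 1e-5 || abs(edf_at(hi) - max_df) < 0.04) break
    }
  }
  lam <- fit$lambda
  lam[j] <- 10^hi
  penfit_refit(fit, lam)
}

#' Wald test for a smooth term
#'
#' Tests whether a fitted smooth term is distinguishable from zero using the
#' Wald statistic \eqn{\beta' V^{-} \beta} on the term's coefficient block,
#' with the pseudo-inverse of its posterior covariance block, referred to a
#' chi-squared distribution with the term's rounded edf as degrees of
#' freedom.
#'
#' @param fit a `"penfit"` object.
#' @param term smooth term label.
#' @return list with `statistic`, `df`, and `p_value` (in `[0, 1]`; a term
#'   with (numerically) zero coefficients or zero edf returns p = 1 with a
#'   `degenerate` flag).
#' @export
wald_smooth_test <- function(fit, term) {
  stopifnot(inherits(fit, "penfit"))
  idx <- fit$blocks[[term]]
  if (is.null(idx)) stop(sprintf("no term '%s' in fit", term))
  beta <- fit$coefficients[idx]
  V <- fit$Vb[idx, idx, drop = FALSE]
  edf <- fit$edf[[term]]
  if (edf < 0.05 || all(abs(beta) < 1e-12)) {
    return(list(statistic = 0, df = 0L, p_value = 1, degenerate = TRUE))
  }
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  tol <- max(eg$values) * 1e-8
  pos <- eg$values > tol
  Vinv_half <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), sum(pos))
  stat <- sum(drop(crossprod(Vinv_half, beta))^2)
  df <- max(1L, as.integer(round(edf)))
  list(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    degenerate = FALSE
  )
}

#' Predict from a penalized fit
#'
#' Evaluates selected components of a `"penfit"` at new covariate values,
#' with optional standard errors from the Bayesian posterior covariance.
#'
#' @param object a `"penfit"`.
#' @param parametric matrix of new parametric columns matching the fit's
#'   parametric block, or `NULL` to exclude it.
#' @param smooth_values named list mapping term labels to new covariate
#'   values (vector for 1-D terms, coordinate matrix for TPRS terms); terms
#'   not named are excluded from the prediction.
#' @param se_fit logical; also return pointwise standard errors.
#' @param ... unused.
#' @return vector of predictions, or list with `fit` and `se` when
#'   `se_fit = TRUE`.
#' @export
predict.penfit <- function(object, parametric = NULL,
                           smooth_values = list(), se_fit = FALSE, ...) {
  labs <- names(smooth_values)
  n_new <- if (!is.null(parametric)) {
    nrow(as.matrix(parametric))
  } else if (length(labs) > 0) {
    v <- smooth_values[[1]]
    if (is.matrix(v) || is.data.frame(v)) nrow(v) else length(v)
  } else {
    stop("nothing to predict: no parametric block and no smooth values")
  }
  Xn <- matrix(0, n_new, ncol(object$X))
  if (!is.null(parametric)) {
    P <- as.matrix(parametric)
    if (ncol(P) == length(object$parametric_names)) {
      P <- P[, object$block_kept$parametric, drop = FALSE]
    }
    if (ncol(P) != length(object$blocks$parametric)) {
      stop("parametric block has the wrong number of columns")
    }
    Xn[, object$blocks$parametric] <- P
  }
  for (lab in labs) {
    idx <- object$blocks[[lab]]
    if (is.null(idx)) stop(sprintf("no term '%s' in fit", lab))
    j <- match(lab, vapply(object$terms, `[[`, "", "label"))
    tm <- object$terms[[j]]
    D <- basis_design(tm$basis, smooth_values[[lab]])
    if (!is.null(tm$Zc)) D <- D %*% tm$Zc
    D <- D[, object$block_kept[[lab]], drop = FALSE]
    Xn[, idx] <- D
  }
  mu <- drop(Xn %*% object$coefficients)
  if (!se_fit) {
    return(mu)
  }
  se <- sqrt(pmax(rowSums((Xn %*% object$Vb) * Xn), 0))
  list(fit = mu, se = se)
}

#' @export
print.penfit <- function(x, ...) {
  cat(sprintf(
    "Penalized fit: n = %d, total edf = %.2f, scale = %.4g, gamma = %.2f\n",
    x$n, x$edf_total, x$scale, x$gamma
  ))
  for (lab in names(x$lambda)) {
    cat(sprintf(
      "  s(%s): lambda = %.3g, edf = %.2f\n", lab, x$lambda[lab], x$edf[lab]
    ))
  }
  invisible(x)
}
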