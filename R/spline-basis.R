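#' Penalized spline bases
#'
#' Low-rank bases for the two kinds of smooth terms used throughout the
#' package: one-dimensional cubic B-spline smooths with a second-order
#' difference penalty (used for covariate effects \eqn{d_q}, \eqn{f_{p,r}}
#' and the temporal smooth \eqn{h(t)}), and bivariate thin-plate regression
#' splines (TPRS, used for all spatial surfaces \eqn{g(s)},
#' \eqn{g_{t,r}(s)}, \eqn{g_{Seas,r}(s)}).
#'
#' @name pmgamm-bases
#' @keywords internal
NULL

#' Build a one-dimensional penalized B-spline basis
#'
#' Constructs a cubic B-spline basis with knots at quantiles of the distinct
#' covariate values and a second-order divided-difference penalty whose null
#' space is exactly the space of linear functions (constant + slope), so that
#' as the smoothing parameter grows the fitted component shrinks to the
#' least-squares line.
#'
#' @param x numeric vector of covariate values (used only for knot placement).
#' @param k basis dimension; reduced (with a warning) when `x` has fewer than
#'   `k` distinct values.
#' @param label optional covariate name carried through fits and reports.
#' @return An object of class `"basis_1d"` with elements `knots`, `k`,
#'   `penalty` (k x k, positive semi-definite, rank k - 2), `null_dim` (2:
#'   constant + linear) and a deterministic design-matrix generator reachable
#'   through [basis_design()].
#' @examples
#' b <- build_basis_1d(runif(100), k = 10)
#' dim(basis_design(b, runif(20)))
#' @export
build_basis_1d <- function(x, k = 10, label = deparse(substitute(x))) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("'x' must be a finite numeric vector")
  }
  if (k < 3) stop("basis dimension 'k' must be at least 3")
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("'x' must contain at least 2 distinct values")
  if (length(ux) < k) {
    warning(sprintf(
      "only %d distinct values for '%s'; reducing basis dimension from %d",
      length(ux), label, k
    ))
    k <- max(3L, length(ux))
  }
  ord <- min(4L, k) # cubic where possible
  n_interior <- k - ord
  interior <- if (n_interior > 0) {
    stats::quantile(ux,
      probs = seq_len(n_interior) / (n_interior + 1),
      names = FALSE, type = 7
    )
  } else {
    numeric(0)
  }
  knots <- c(rep(ux[1], ord), interior, rep(ux[length(ux)], ord))
  greville <- vapply(seq_len(k), function(i) {
    mean(knots[(i + 1):(i + ord - 1)])
  }, numeric(1))
  obj <- structure(
    list(
      label = label, k = k, order = ord, knots = knots,
      greville = greville, range = range(ux),
      penalty = divided_diff_penalty(greville),
      null_dim = 2L
    ),
    class = "basis_1d"
  )
  obj
}

# Second-order divided-difference penalty on the Greville abscissae.
# Null space: coefficient vectors linear in the Greville positions, which by
# the Marsden identity correspond exactly to linear functions of x.
divided_diff_penalty <- function(g) {
  k <- length(g)
  if (k < 3) {
    return(matrix(0, k, k))
  }
  D <- matrix(0, k - 2, k)
  for (i in seq_len(k - 2)) {
    h1 <- g[i + 1] - g[i]
    h2 <- g[i + 2] - g[i + 1]
    # second divided difference, scaled by the average spacing so the
    # penalty has the magnitude of an integrated squared second derivative
    w <- sqrt((h1 + h2) / 2)
    D[i, i] <- w * 2 / (h1 * (h1 + h2))
    D[i, i + 1] <- -w * 2 / (h1 * h2)
    D[i, i + 2] <- w * 2 / (h2 * (h1 + h2))
  }
  S <- crossprod(D)
  (S + t(S)) / 2
}

#' Build a bivariate thin-plate regression spline basis
#'
#' Eigen-truncated thin-plate construction: the radial kernel
#' \eqn{\eta(r) = r^2 \log r} is evaluated on the distinct construction
#' points, the kernel matrix is eigen-decomposed, the leading `k` directions
#' are retained, and the 3-dimensional polynomial null space (constant + two
#' linear coordinates) is separated out so the penalty annihilates it
#' exactly.  For more than `max_knots` distinct points a deterministic
#' farthest-point subset is used for construction.
#'
#' @param coords two-column matrix (or data frame) of planar coordinates.
#' @param k total basis dimension including the 3 null-space functions;
#'   must satisfy `4 <= k <=` number of distinct construction points.
#' @param max_knots construction-point budget (default 600); larger inputs
#'   are thinned by a space-filling (farthest-point) rule.
#' @param label optional name for reports.
#' @return An object of class `"basis_tprs"` with the truncated basis,
#'   its penalty (positive semi-definite, rank k - 3), and `null_dim = 3`.
#' @export
build_basis_tprs <- function(coords, k = 30, max_knots = 600,
                             label = "space") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || !all(is.finite(coords))) {
    stop("'coords' must be a finite n x 2 matrix")
  }
  pts <- unique(coords)
  if (nrow(pts) < 2) stop("all coordinates are duplicates of a single point")
  if (k < 4) stop("TPRS basis dimension 'k' must be at least 4")
  if (nrow(pts) > max_knots) {
    pts <- pts[farthest_point_subset(pts, max_knots), , drop = FALSE]
  }
  # standardize construction coordinates to a unit box for conditioning
  rng_orig <- apply(pts, 2, range)
  cshift <- colMeans(pts)
  cscale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  pts <- sweep(pts, 2, cshift) / cscale
  if (k > nrow(pts)) {
    warning(sprintf(
      "k = %d exceeds %d distinct construction points; reducing",
      k, nrow(pts)
    ))
    k <- nrow(pts)
  }
  E <- tprs_kernel(pts, pts)
  Tm <- cbind(1, pts)
  eg <- eigen(E, symmetric = TRUE)
  keep <- order(abs(eg$values), decreasing = TRUE)[seq_len(k)]
  U_k <- eg$vectors[, keep, drop = FALSE]
  d_k <- eg$values[keep]
  # absorb the orthogonality constraint T' delta = 0
  A <- t(crossprod(Tm, U_k)) # k x 3
  qrA <- qr(A)
  Z <- qr.Q(qrA, complete = TRUE)[, (qrA$rank + 1):k, drop = FALSE]
  nw <- ncol(Z) # k - 3 for non-degenerate geometry
  S <- crossprod(Z, d_k * Z)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    warning("TPRS penalty has a materially negative eigenvalue; clipping")
  }
  # full penalty over [wiggly block, 3 unpenalized polynomial columns]
  Sfull <- matrix(0, nw + 3, nw + 3)
  Sfull[seq_len(nw), seq_len(nw)] <- S
  structure(
    list(
      label = label, k = nw + 3L, points = pts,
      cshift = cshift, cscale = cscale,
      UZ = U_k %*% Z, # maps wiggly coefficients to kernel coefficients
      penalty = Sfull, null_dim = 3L,
      range = rng_orig
    ),
    class = "basis_tprs"
  )
}

tprs_kernel <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  r2 <- pmax(d2, 0)
  out <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0) # r^2 log r, eta(0) = 0
  out
}

# Deterministic space-filling subset: start from the point nearest the
# centroid, then repeatedly add the point farthest from the current set.
farthest_point_subset <- function(pts, m) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  d0 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
  sel <- integer(m)
  sel[1] <- which.min(d0)
  mind <- (pts[, 1] - pts[sel[1], 1])^2 + (pts[, 2] - pts[sel[1], 2])^2
  for (i in 2:m) {
    sel[i] <- which.max(mind)
    di <- (pts[, 1] - pts[sel[i], 1])^2 + (pts[, 2] - pts[sel[i], 2])^2
    mind <- pmin(mind, di)
  }
  sort(sel)
}

#' Evaluate a basis design matrix
#'
#' Deterministic generator mapping covariate values (or coordinates) to the
#' n x k design matrix of the basis.  One-dimensional bases clamp evaluation
#' points to the knot range (prediction-time covariates are clamped to
#' training ranges anyway, see [clamp_covariates()]).
#'
#' @param basis a `"basis_1d"` or `"basis_tprs"` object.
#' @param x numeric vector (1-D) or n x 2 coordinate matrix (TPRS).
#' @return numeric matrix with `basis$k` columns.
#' @export
basis_design <- function(basis, x) {
  UseMethod("basis_design")
}

#' @export
basis_design.basis_1d <- function(basis, x) {
  x <- pmin(pmax(as.numeric(x), basis$range[1]), basis$range[2])
  splines::splineDesign(basis$knots, x, ord = basis$order)
}

#' @export
basis_design.basis_tprs <- function(basis, x) {
  x <- as.matrix(x)
  x <- sweep(x, 2, basis$cshift) / basis$cscale
  Ex <- tprs_kernel(x, basis$points)
  cbind(Ex %*% basis$UZ, 1, x)
}

#' @export
print.basis_1d <- function(x, ...) {
  cat(sprintf(
    "1-D penalized B-spline basis '%s': k = %d, %d interior knots\n",
    x$label, x$k, length(x$knots) - 2 * x$order
  ))
  invisible(x)
}

#' @export
print.basis_tprs <- function(x, ...) {
  cat(sprintf(
    "TPRS basis '%s': k = %d (3-dim polynomial null space), %d knots\n",
    x$label, x$k, nrow(x$points)
  ))
  invisible(x)
}
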