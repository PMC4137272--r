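#' Covariate construction and transformation
#'
#' Builds the geographic covariates the exposure models use: log-shift and
#' square-root-shift transforms for right-skewed quantities, quadratic-kernel
#' densities for traffic and point-source emissions, distance-to-road
#' truncation, cardinal-cell raster averaging, and thin-plate smoothing of
#' point values (county-centroid population density).  Every transform
#' records the metadata needed to apply the identical mapping at prediction
#' time.
#'
#' @name pmgamm-covariates
#' @keywords internal
NULL

#' Log-shift transform for right-skewed covariates
#'
#' Returns `ln(z - min(z) + shift)`.  The shift constant (default 10) keeps
#' values near zero from exerting high leverage on the spline smooths.  The
#' training minimum and shift are recorded so the identical mapping can be
#' applied to prediction-time data (always reusing the training minimum).
#'
#' @param z finite numeric vector.
#' @param shift positive shift constant (default 10).
#' @return numeric vector with attributes `min` and `shift`; see
#'   [apply_transform()].
#' @examples
#' log_shift_transform(c(0, 90)) # ln(10), ln(100)
#' @export
log_shift_transform <- function(z, shift = 10) {
  if (!all(is.finite(z))) stop("non-finite values in 'z'")
  if (shift <= 0) stop("'shift' must be positive")
  m <- min(z)
  out <- log(z - m + shift)
  attr(out, "transform") <- "log_shift"
  attr(out, "min") <- m
  attr(out, "shift") <- shift
  out
}

#' Square-root-shift transform (elevation)
#'
#' Returns `sqrt(z - min(z) + 1)`: a square-root transform after adding a
#' constant so the minimum transformed argument is one.  Training minimum is
#' recorded for prediction-time reuse.
#'
#' @param elev finite numeric vector (elevation, any length unit).
#' @return transformed vector with attributes `min` and `shift` (= 1).
#' @examples
#' sqrt_shift_transform(c(0, 3, 99)) # 1, 2, 10
#' @export
sqrt_shift_transform <- function(elev) {
  if (!all(is.finite(elev))) stop("non-finite values in 'elev'")
  m <- min(elev)
  out <- sqrt(elev - m + 1)
  attr(out, "transform") <- "sqrt_shift"
  attr(out, "min") <- m
  attr(out, "shift") <- 1
  out
}

#' Apply a recorded transform to new data
#'
#' Reapplies the mapping recorded by [log_shift_transform()] or
#' [sqrt_shift_transform()] to prediction-time values, using the *training*
#' minimum (never recomputed on new data), so training and prediction
#' covariates live on the identical scale.
#'
#' @param z new values.
#' @param meta a transformed vector (carrying attributes) or a list with
#'   `transform`, `min`, `shift`.
#' @return transformed values.
#' @export
apply_transform <- function(z, meta) {
  tr <- if (is.list(meta)) meta$transform else attr(meta, "transform")
  m <- if (is.list(meta)) meta$min else attr(meta, "min")
  s <- if (is.list(meta)) meta$shift else attr(meta, "shift")
  switch(tr,
    log_shift = log(pmax(z - m + s, .Machine$double.eps)),
    sqrt_shift = sqrt(pmax(z - m + s, 0)),
    stop(sprintf("unknown transform '%s'", tr))
  )
}

#' Quadratic (biweight) kernel density of weighted points
#'
#' Density at location \eqn{s}: \eqn{\sum_j w_j \frac{3}{\pi h^2} (1 -
#' (d_j/h)^2)^2} for \eqn{d_j < h}, zero otherwise — the quadratic-kernel
#' density used for traffic and point-source emissions, which down-weights
#' more distant sources inside the neighborhood `bandwidth` and integrates
#' to the total weight.
#'
#' @param points n x 2 matrix of source locations.
#' @param weights nonnegative source weights (negative weights are accepted
#'   only with `allow_negative = TRUE` and flagged).
#' @param bandwidth kernel radius h > 0 (same length unit as coordinates).
#' @param eval_locations m x 2 matrix of evaluation locations.
#' @param allow_negative allow signed weights (flagged in the result).
#' @return density vector (weight per squared length unit) of length m.
#' @export
quadratic_kernel_density <- function(points, weights, bandwidth,
                                     eval_locations,
                                     allow_negative = FALSE) {
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  eval_locations <- as.matrix(eval_locations)
  if (is.null(points) || NROW(points) == 0) {
    return(rep(0, nrow(eval_locations)))
  }
  points <- as.matrix(points)
  if (length(weights) == 1) weights <- rep(weights, nrow(points))
  neg <- any(weights < 0)
  if (neg && !allow_negative) stop("negative weights (set allow_negative)")
  d2 <- outer(eval_locations[, 1], points[, 1], "-")^2 +
    outer(eval_locations[, 2], points[, 2], "-")^2
  u2 <- d2 / bandwidth^2
  K <- ifelse(u2 < 1, 3 / (pi * bandwidth^2) * (1 - u2)^2, 0)
  out <- drop(K %*% weights)
  if (neg) attr(out, "signed_weights") <- TRUE
  out
}

#' Truncate distance-to-road values
#'
#' Distances are capped at `cap` (500 m by default), so the covariate
#' represents only micro- to middle-scale variability near roadways.
#'
#' @param d nonnegative distances in meters.
#' @param cap truncation value in meters.
#' @return `pmin(d, cap)`.
#' @export
truncate_distance <- function(d, cap = 500) {
  if (any(d < 0)) stop("negative distances")
  pmin(d, cap)
}

#' Cardinal-cell raster averaging
#'
#' Replaces each raster cell with the mean of itself and its four cardinal
#' neighbors (edge cells average over the neighbors that exist), reducing
#' spatial discontinuities across cells of gridded density covariates.
#'
#' @param grid numeric matrix, at least 3 x 3.
#' @return matrix of the same dimension.
#' @export
cardinal_cell_average <- function(grid) {
  grid <- as.matrix(grid)
  nr <- nrow(grid)
  nc <- ncol(grid)
  if (nr < 3 || nc < 3) stop("grid must be at least 3 x 3")
  tot <- grid
  cnt <- matrix(1, nr, nc)
  # up / down / left / right shifts, accumulated where the neighbor exists
  tot[-1, ] <- tot[-1, ] + grid[-nr, ]
  cnt[-1, ] <- cnt[-1, ] + 1
  tot[-nr, ] <- tot[-nr, ] + grid[-1, ]
  cnt[-nr, ] <- cnt[-nr, ] + 1
  tot[, -1] <- tot[, -1] + grid[, -nc]
  cnt[, -1] <- cnt[, -1] + 1
  tot[, -nc] <- tot[, -nc] + grid[, -1]
  cnt[, -nc] <- cnt[, -nc] + 1
  tot / cnt
}

#' Moving-window (circular) raster averaging
#'
#' Mean over all cells whose centers fall within `radius` of each cell
#' center — the moving-window smoothing applied to gridded elevation.
#'
#' @param grid numeric matrix.
#' @param radius window radius in cell-size units.
#' @param cellsize cell edge length (default 1).
#' @return smoothed matrix.
#' @export
circular_window_average <- function(grid, radius, cellsize = 1) {
  grid <- as.matrix(grid)
  r_cells <- floor(radius / cellsize)
  offs <- expand.grid(di = -r_cells:r_cells, dj = -r_cells:r_cells)
  offs <- offs[(offs$di^2 + offs$dj^2) * cellsize^2 <= radius^2, ]
  nr <- nrow(grid)
  nc <- ncol(grid)
  tot <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (o in seq_len(nrow(offs))) {
    di <- offs$di[o]
    dj <- offs$dj[o]
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di
    sj <- rj - dj
    tot[ri, rj] <- tot[ri, rj] + grid[si, sj]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  tot / cnt
}

#' Thin-plate smooth of scattered point values
#'
#' Fits a GCV-selected thin-plate smooth surface to values observed at
#' scattered points (e.g. county-centroid population density) and returns a
#' prediction function evaluable anywhere.  Degenerate (collinear-only)
#' geometry falls back to a planar ordinary-least-squares fit with a
#' warning.
#'
#' @param coords n x 2 point locations.
#' @param values numeric values at the points.
#' @param k TPRS basis dimension (default `min(n - 1, 200)`).
#' @param gamma GCV multiplier.
#' @return object of class `"point_smooth"` with `$predict(newcoords)`.
#' @export
smooth_point_values <- function(coords, values, k = NULL, gamma = 1.4) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 points")
  span <- apply(coords, 2, function(v) diff(range(v)))
  res <- stats::residuals(stats::lm(coords[, 2] ~ coords[, 1]))
  if (all(span > 0) && stats::sd(res) < 1e-10 * max(span)) {
    warning("collinear point geometry; using planar fit")
    pl <- stats::lm(values ~ coords[, 1] + coords[, 2])
    cf <- stats::coef(pl)
    cf[is.na(cf)] <- 0
    return(structure(
      list(
        planar = TRUE,
        predict = function(nc) {
          nc <- as.matrix(nc)
          cf[1] + cf[2] * nc[, 1] + cf[3] * nc[, 2]
        }
      ),
      class = "point_smooth"
    ))
  }
  if (is.null(k)) k <- min(n - 1, 200)
  b <- build_basis_tprs(coords, k = k, label = "surface")
  fit <- fit_penalized(values,
    smooths = list(smooth_term(b, coords, "surface")), gamma = gamma
  )
  structure(
    list(
      planar = FALSE, fit = fit, basis = b,
      predict = function(nc) {
        predict(fit,
          parametric = matrix(1, nrow(as.matrix(nc)), 1),
          smooth_values = list(surface = as.matrix(nc))
        )
      }
    ),
    class = "point_smooth"
  )
}

#' Read / write plain-text rasters (ESRI ASCII grid convention)
#'
#' Minimal reader and writer for the 6-line-header ASCII grid format
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' used for exchanging small gridded covariates as text.
#'
#' @param path file path.
#' @return `read_ascii_grid`: list with `grid` (matrix, row 1 = northern
#'   row), `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- as.integer(kv(1))
  nrows <- as.integer(kv(2))
  vals <- scan(path, skip = 6, quiet = TRUE)
  grid <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- kv(6)
  grid[grid == nodata] <- NA
  list(
    grid = grid, xllcorner = kv(3), yllcorner = kv(4),
    cellsize = kv(5), nodata = nodata
  )
}

#' @rdname read_ascii_grid
#' @param grid numeric matrix (row 1 = northern row).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell edge length.
#' @param nodata value standing in for `NA`.
#' @export
write_ascii_grid <- function(grid, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  grid <- as.matrix(grid)
  grid[is.na(grid)] <- nodata
  hdr <- c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    paste("xllcorner", xllcorner),
    paste("yllcorner", yllcorner),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  body <- apply(grid, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
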