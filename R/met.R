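#' Meteorological surface smoothing
#'
#' Station meteorology (wind speed, temperature, precipitation, air
#' stagnation) enters the exposure models as predicted values from monthly,
#' regional spatial surfaces: for each parameter, month and region the
#' station values are fit with a bivariate thin-plate smooth
#' \eqn{y_{i,t} = \alpha_{t,r} + g_{t,r}(s_i) + e_{i,t}} whose basis
#' dimension scales with the station count, \eqn{k_{t,r} = \lfloor I_{t,r}
#' \cdot 0.9 \rfloor}, and whose smoothing is guarded by the gamma
#' multiplier 1.4.  Air-stagnation fractions are natural-log transformed
#' (after a +0.5 percentage-point shift to cover zero months) before
#' smoothing.
#'
#' @name pmgamm-met
#' @keywords internal
NULL

#' Fit one meteorological surface (one parameter, month, region)
#'
#' @param panel data frame with columns `station_id`, `x`, `y`, `value` for
#'   a single parameter / month / region.
#' @param parameter parameter name; `"stagnation"` values are log-transformed
#'   (with a +0.5 shift, recorded in the result) before fitting.
#' @param month,region identifiers carried into the result.
#' @param gamma GCV multiplier (default 1.4).
#' @param k_factor basis-dimension fraction of the station count (0.9).
#' @return object of class `"met_surface"`; fewer than 5 stations yields a
#'   constant-mean surface with a warning.
#' @export
fit_met_surface <- function(panel, parameter = "met", month = NA,
                            region = NA, gamma = 1.4, k_factor = 0.9) {
  stopifnot(all(c("x", "y", "value") %in% names(panel)))
  ok <- is.finite(panel$value)
  panel <- panel[ok, , drop = FALSE]
  vals <- panel$value
  logged <- FALSE
  if (identical(parameter, "stagnation")) {
    vals <- log(vals + 0.5)
    logged <- TRUE
  }
  n <- nrow(panel)
  coords <- as.matrix(panel[, c("x", "y")])
  if (n < 5) {
    warning(sprintf(
      "only %d stations for %s month %s region %s; constant-mean surface",
      n, parameter, month, region
    ))
    return(structure(
      list(
        parameter = parameter, month = month, region = region,
        constant = mean(vals), const_se = stats::sd(vals) / sqrt(max(n, 1)),
        fit = NULL, n_stations = n, logged = logged,
        bbox = apply(coords, 2, range), k = NA_integer_
      ),
      class = "met_surface"
    ))
  }
  n_distinct <- nrow(unique(coords))
  k <- max(4L, min(as.integer(floor(n * k_factor)), n_distinct, n - 1L))
  b <- build_basis_tprs(coords, k = k, label = "space")
  fit <- fit_penalized(vals,
    smooths = list(smooth_term(b, coords, "space")),
    gamma = gamma
  )
  structure(
    list(
      parameter = parameter, month = month, region = region,
      constant = NULL, fit = fit, n_stations = n, logged = logged,
      bbox = apply(coords, 2, range), k = k,
      alpha = mean(vals)
    ),
    class = "met_surface"
  )
}

#' Predict from a fitted meteorological surface
#'
#' Evaluates the fitted monthly regional surface at arbitrary locations.
#' Predictions well outside the training bounding box (by more than half its
#' diagonal) trigger an extrapolation warning.  Log-fitted parameters
#' (stagnation) are returned on the log scale used in model fitting.
#'
#' @param surface a `"met_surface"`.
#' @param locations m x 2 coordinate matrix.
#' @param se_fit also return standard errors.
#' @return predictions (or list `fit`, `se`).
#' @export
predict_met <- function(surface, locations, se_fit = FALSE) {
  stopifnot(inherits(surface, "met_surface"))
  locations <- as.matrix(locations)
  bb <- surface$bbox
  diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  over <- pmax(bb[1, 1] - locations[, 1], locations[, 1] - bb[2, 1], 0) +
    pmax(bb[1, 2] - locations[, 2], locations[, 2] - bb[2, 2], 0)
  if (any(over > 0.5 * diag_len)) {
    warning("predicting far outside the training bounding box")
  }
  if (!is.null(surface$constant)) {
    mu <- rep(surface$constant, nrow(locations))
    if (!se_fit) {
      return(mu)
    }
    return(list(fit = mu, se = rep(surface$const_se, nrow(locations))))
  }
  predict(surface$fit,
    parametric = matrix(1, nrow(locations), 1),
    smooth_values = list(space = locations), se_fit = se_fit
  )
}

#' Fit all meteorological surfaces in a station panel
#'
#' Convenience wrapper: fits [fit_met_surface()] for every combination of
#' parameter, month and region present in a long-format meteorology panel.
#'
#' @param met_panel data frame with columns `station_id`, `x`, `y`,
#'   `region`, `month`, `parameter`, `value`.
#' @param gamma named vector of per-region gamma multipliers or a single
#'   value (default 1.4).
#' @return nested list `surfaces[[parameter]][[region]][[month]]`.
#' @export
fit_met_surfaces <- function(met_panel, gamma = 1.4) {
  need <- c("station_id", "x", "y", "region", "month", "parameter", "value")
  stopifnot(all(need %in% names(met_panel)))
  out <- list()
  for (par in unique(met_panel$parameter)) {
    out[[par]] <- list()
    sub_p <- met_panel[met_panel$parameter == par, ]
    for (r in unique(sub_p$region)) {
      g_r <- if (length(gamma) > 1) gamma[[as.character(r)]] else gamma
      sub_r <- sub_p[sub_p$region == r, ]
      out[[par]][[as.character(r)]] <- lapply(
        stats::setNames(nm = sort(unique(sub_r$month))),
        function(m) {
          fit_met_surface(sub_r[sub_r$month == m, ],
            parameter = par, month = m, region = r, gamma = g_r
          )
        }
      )
    }
  }
  out
}
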