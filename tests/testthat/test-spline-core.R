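# Penalized-spline engine: bases, penalties, GCV selection, edf, Wald.

test_that("1-D basis has the advertised dimensions and penalty structure", {
  x <- seq(0, 1, length.out = 100)
  b <- build_basis_1d(x, k = 10)
  D <- basis_design(b, x)
  expect_equal(dim(D), c(100, 10))
  expect_equal(qr(D)$rank, 10)
  # penalty symmetric PSD with rank k - 2 (constant + linear null space)
  expect_equal(b$penalty, t(b$penalty))
  ev <- eigen(b$penalty, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8 * max(ev))
  expect_equal(sum(ev > 1e-8 * max(ev)), 8)
  expect_equal(b$null_dim, 2L)
})

test_that("too few distinct values downgrade k with a warning; k < 3 errors", {
  x <- rep(1:5, 10)
  expect_warning(b <- build_basis_1d(x, k = 10), "distinct")
  expect_equal(b$k, 5L)
  expect_error(build_basis_1d(runif(10), k = 2), "at least 3")
})

test_that("infinite smoothing reduces a 1-D fit to the least-squares line", {
  set.seed(1)
  x <- sort(runif(80)) # deliberately non-uniform spacing
  y <- sin(2 * pi * x) + rnorm(80, 0, 0.2)
  b <- build_basis_1d(x, k = 10)
  f <- fit_penalized(y, list(smooth_term(b, x, "x", lambda = 1e9)))
  expect_lt(max(abs(f$fitted - fitted(lm(y ~ x)))), 1e-5)
  expect_equal(f$edf_total, 2, tolerance = 1e-3)
})

test_that("TPRS basis: eigen truncation, polynomial null space, k rules", {
  set.seed(2)
  co <- matrix(runif(100, 0, 1000), 50, 2)
  b <- build_basis_tprs(co, k = 20)
  expect_equal(b$k, 20L)
  expect_equal(b$null_dim, 3L)
  # penalty annihilates the polynomial columns (last 3 of the design)
  expect_true(all(b$penalty[, (b$k - 2):b$k] == 0))
  ev <- eigen(b$penalty, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8 * max(ev))
  # k = ceil(n * 0.9) convention used for the monthly surfaces
  expect_equal(floor(100 * 0.9), 90)
  expect_error(build_basis_tprs(matrix(1, 5, 2), 4), "duplicates")
})

test_that("infinite smoothing reduces a TPRS fit to the planar regression", {
  set.seed(3)
  co <- matrix(runif(100, 0, 1000), 50, 2)
  y <- 1 + 0.002 * co[, 1] - 0.003 * co[, 2] + rnorm(50, 0, 0.1)
  b <- build_basis_tprs(co, k = 20)
  f <- fit_penalized(y, list(smooth_term(b, co, "s", lambda = 1e9)))
  expect_lt(max(abs(f$fitted - fitted(lm(y ~ co[, 1] + co[, 2])))), 1e-6)
})

test_that("a saturated TPRS basis with zero penalty interpolates", {
  set.seed(4)
  co <- matrix(runif(30, 0, 500), 15, 2)
  y <- rnorm(15)
  b <- build_basis_tprs(co, k = 15)
  f <- fit_penalized(y,
    list(smooth_term(b, co, "s", lambda = 0, center = FALSE)),
    parametric = matrix(numeric(0), 15, 0)
  )
  expect_lt(max(abs(f$residuals)) / max(abs(y)), 1e-8)
})

test_that("fixed-lambda fits equal the closed-form penalized solution", {
  set.seed(5)
  x <- runif(60)
  y <- cos(3 * x) + rnorm(60, 0, 0.3)
  b <- build_basis_1d(x, k = 10)
  f <- fit_penalized(y, list(smooth_term(b, x, "x", lambda = 3.7)))
  # oracle: closed-form (X'X + lambda S)^{-1} X'y with the fit's own
  # constrained design and balanced penalty
  X <- f$X
  S <- matrix(0, ncol(X), ncol(X))
  idx <- f$blocks$x
  S[idx, idx] <- 3.7 * f$pen_list[[1]]$S
  beta <- solve(crossprod(X) + S, crossprod(X, y))
  expect_lt(max(abs(X %*% beta - f$fitted)) / max(abs(y)), 1e-8)
  # edf equals the explicit influence-matrix trace
  H <- X %*% solve(crossprod(X) + S, t(X))
  expect_equal(f$edf_total, sum(diag(H)), tolerance = 1e-6)
})

test_that("the gamma multiplier is monotone: edf(1.4) <= edf(1.0)", {
  set.seed(6)
  x <- runif(150)
  y <- sin(2 * pi * x) + rnorm(150, 0, 0.3)
  b <- build_basis_1d(x, k = 10)
  e14 <- fit_penalized(y, list(smooth_term(b, x, "x")),
    gamma = 1.4)$edf_total
  e10 <- fit_penalized(y, list(smooth_term(b, x, "x")),
    gamma = 1.0)$edf_total
  expect_lte(e14, e10 + 1e-8)
})

test_that("GCV with gamma = 1.4 shrinks pure-noise smooths toward the
           null space", {
  set.seed(7)
  x <- runif(100)
  b <- build_basis_1d(x, k = 10)
  edfs <- replicate(30, {
    y <- rnorm(100)
    fit_penalized(y, list(smooth_term(b, x, "x")), gamma = 1.4)$edf[["x"]]
  })
  # centered term's null space is 1-dimensional (linear); mean edf within 1
  expect_lt(abs(mean(edfs) - 1), 1)
})

test_that("cap_edf lowers a selected edf to the ceiling and leaves
           compliant fits unchanged", {
  set.seed(8)
  x <- runif(300)
  y <- sin(4 * pi * x) + rnorm(300, 0, 0.15)
  b <- build_basis_1d(x, k = 10)
  f <- fit_penalized(y, list(smooth_term(b, x, "x")), gamma = 1)
  expect_gt(f$edf[["x"]], 6) # strong signal picks a wiggly fit
  fc <- cap_edf(f, "x", 6)
  expect_lte(fc$edf[["x"]], 6 + 1e-6)
  expect_gte(fc$edf[["x"]], 5.9)
  f2 <- cap_edf(fc, "x", 8)
  expect_identical(f2$lambda, fc$lambda)
  expect_error(cap_edf(f, "x", 0.5), "null-space")
})

test_that("cap at the null-space dimension drives the component linear", {
  set.seed(9)
  x <- runif(100)
  y <- sin(2 * pi * x) + rnorm(100, 0, 0.1)
  b <- build_basis_1d(x, k = 10)
  f <- fit_penalized(y, list(smooth_term(b, x, "x")), gamma = 1)
  fc <- cap_edf(f, "x", 1) # centered null space: the linear direction
  grid <- seq(0.1, 0.9, length.out = 30)
  comp <- predict(fc, smooth_values = list(x = grid))
  expect_lt(max(abs(residuals(lm(comp ~ grid)))), 1e-3)
})

test_that("Wald test: strong effects give tiny p, zero blocks give p = 1", {
  set.seed(10)
  x <- runif(200)
  y <- 1.5 * sin(2 * pi * x) + rnorm(200, 0, 0.3)
  b <- build_basis_1d(x, k = 10)
  f <- fit_penalized(y, list(smooth_term(b, x, "x")), gamma = 1.4)
  expect_lt(wald_smooth_test(f, "x")$p_value, 1e-6)
  f0 <- f
  f0$coefficients[f0$blocks$x] <- 0
  w0 <- wald_smooth_test(f0, "x")
  expect_equal(w0$p_value, 1)
  expect_true(w0$degenerate)
})

test_that("posterior covariance reproduces sampling variability of a
           fixed-lambda smoother", {
  set.seed(11)
  n <- 60
  x <- runif(n)
  b <- build_basis_1d(x, k = 8)
  mu <- sin(2 * pi * x)
  # light smoothing: posterior and sampling covariances coincide up to
  # Monte-Carlo error (heavier smoothing adds bias terms the Bayesian
  # covariance covers but the sampling covariance does not)
  lam <- 1e-4
  f0 <- fit_penalized(mu + rnorm(n, 0, 0.5),
    list(smooth_term(b, x, "x", lambda = lam)))
  idx <- f0$blocks$x
  betas <- replicate(500, {
    f <- fit_penalized(mu + rnorm(n, 0, 0.5),
      list(smooth_term(b, x, "x", lambda = lam)))
    f$coefficients[idx]
  })
  emp <- cov(t(betas))
  theo <- f0$Vb[idx, idx] / f0$scale * 0.25 # exact sigma^2 = 0.25
  expect_lt(
    norm(emp - theo, "F") / norm(theo, "F"), 0.15
  )
})

test_that("rank-deficient designs drop dependent columns with a warning", {
  set.seed(12)
  x <- runif(50)
  P <- cbind(1, x, x) # duplicated column
  expect_warning(
    f <- fit_penalized(rnorm(50), parametric = P),
    "dependent"
  )
  expect_equal(length(f$coefficients), 2)
})

test_that("independent cross-check: GCV fit agrees with mgcv on the same
           data", {
  skip_if_not_installed("mgcv")
  set.seed(13)
  x <- runif(200)
  y <- sin(2 * pi * x) + rnorm(200, 0, 0.25)
  b <- build_basis_1d(x, k = 10)
  f <- fit_penalized(y, list(smooth_term(b, x, "x")), gamma = 1.4)
  g <- mgcv::gam(y ~ s(x, k = 10), gamma = 1.4)
  expect_gt(cor(f$fitted, fitted(g)), 0.995)
  expect_lt(abs(f$edf_total - sum(g$edf)), 2.5)
})
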