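# Covariate transforms, kernel densities, raster smoothing.

test_that("log-shift transform matches its closed form and records
           metadata", {
  z <- c(0, 90)
  tr <- log_shift_transform(z)
  expect_equal(as.numeric(tr), c(log(10), log(100)))
  expect_equal(attr(tr, "min"), 0)
  expect_equal(attr(tr, "shift"), 10)
  # constant vector maps to log(shift)
  expect_equal(as.numeric(log_shift_transform(c(5, 5, 5))), rep(log(10), 3))
  # strict monotonicity preserves rank order
  set.seed(1)
  z2 <- rnorm(50, 0, 20)
  expect_equal(rank(as.numeric(log_shift_transform(z2))), rank(z2))
  expect_error(log_shift_transform(c(1, NA)), "non-finite")
})

test_that("sqrt-shift transform matches its closed form", {
  expect_equal(as.numeric(sqrt_shift_transform(c(0, 3, 99))), c(1, 2, 10))
  expect_equal(as.numeric(sqrt_shift_transform(c(7, 7))), c(1, 1))
  set.seed(2)
  e <- runif(30, 0, 3000)
  expect_equal(rank(as.numeric(sqrt_shift_transform(e))), rank(e))
})

test_that("prediction-time transforms reuse the training minimum", {
  z_train <- c(2, 10, 50)
  tr <- log_shift_transform(z_train)
  # a new value below the training min still uses the training min
  z_new <- c(0, 2, 100)
  expect_equal(
    apply_transform(z_new, tr),
    log(z_new - 2 + 10)
  )
  # bit-for-bit reproducibility on the training data itself
  expect_identical(apply_transform(z_train, tr), as.numeric(tr))
})

test_that("quadratic kernel density: closed form, support, linearity", {
  pt <- matrix(c(0, 0), 1, 2)
  # at the source point the kernel equals 3 / (pi h^2)
  expect_equal(
    quadratic_kernel_density(pt, 1, 100, pt),
    3 / (pi * 100^2)
  )
  # zero beyond the bandwidth
  far <- matrix(c(150, 0), 1, 2)
  expect_equal(quadratic_kernel_density(pt, 1, 100, far), 0)
  # doubling weights doubles the density
  set.seed(3)
  pts <- matrix(runif(20, 0, 500), 10, 2)
  ev <- matrix(runif(10, 0, 500), 5, 2)
  w <- runif(10, 0.5, 2)
  expect_equal(
    quadratic_kernel_density(pts, 2 * w, 200, ev),
    2 * quadratic_kernel_density(pts, w, 200, ev)
  )
  # no points -> zero vector
  expect_equal(quadratic_kernel_density(NULL, 1, 100, ev), rep(0, 5))
  expect_error(quadratic_kernel_density(pt, -1, 100, pt), "negative")
})

test_that("kernel density integrates to the total weight", {
  pts <- matrix(c(0, 0, 50, 30), 2, 2, byrow = TRUE)
  w <- c(2, 3)
  h <- 40
  gr <- as.matrix(expand.grid(
    x = seq(-60, 120, by = 1), y = seq(-60, 100, by = 1)
  ))
  dens <- quadratic_kernel_density(pts, w, h, gr)
  expect_equal(sum(dens) * 1, sum(w), tolerance = 0.01)
})

test_that("distance truncation caps at 500 m", {
  expect_equal(
    truncate_distance(c(10, 499, 500, 12000)),
    c(10, 499, 500, 500)
  )
  expect_equal(truncate_distance(rep(0, 4)), rep(0, 4))
  set.seed(4)
  expect_true(all(truncate_distance(rexp(100, 1 / 400)) <= 500))
  expect_error(truncate_distance(c(-1, 5)), "negative")
})

test_that("cardinal-cell averaging: constants, spikes, mean preservation", {
  g <- matrix(3, 5, 5)
  expect_equal(cardinal_cell_average(g), g)
  sp <- matrix(0, 5, 5)
  sp[3, 3] <- 5
  av <- cardinal_cell_average(sp)
  expect_equal(av[3, 3], 1)
  expect_equal(av[2, 3], 1)
  expect_equal(av[3, 2], 1)
  expect_equal(av[2, 2], 0)
  # interior-dominated grids preserve the global mean approximately
  set.seed(5)
  big <- matrix(runif(40 * 40), 40, 40)
  expect_equal(
    mean(cardinal_cell_average(big)), mean(big),
    tolerance = 0.01
  )
  expect_error(cardinal_cell_average(matrix(1, 2, 2)), "3 x 3")
})

test_that("circular-window averaging is a local mean", {
  g <- matrix(7, 9, 9)
  expect_equal(circular_window_average(g, radius = 2), g)
  sp <- matrix(0, 9, 9)
  sp[5, 5] <- 1
  av <- circular_window_average(sp, radius = 1.2)
  # window of radius 1.2 cells covers 5 cells (self + cardinals)
  expect_equal(av[5, 5], 1 / 5)
  # radius 1.5 additionally reaches the diagonals (distance ~1.41)
  expect_equal(circular_window_average(sp, radius = 1.5)[5, 5], 1 / 9)
})

test_that("point-value smoothing recovers planes exactly and bumps
           approximately", {
  set.seed(6)
  co <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  vp <- 2 + 0.05 * co[, 1] - 0.02 * co[, 2]
  sm <- smooth_point_values(co, vp)
  nc <- cbind(runif(30, 10, 90), runif(30, 10, 90))
  expect_lt(max(abs(sm$predict(nc) - (2 + 0.05 * nc[, 1] -
    0.02 * nc[, 2]))), 1e-4)
  # bump recovery within 10% of the amplitude
  set.seed(7)
  co2 <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  bump <- function(m) 2 * exp(-((m[, 1] - 50)^2 + (m[, 2] - 50)^2) / 500)
  v2 <- bump(co2) + rnorm(200, 0, 0.1)
  sm2 <- smooth_point_values(co2, v2)
  nc2 <- cbind(runif(100, 15, 85), runif(100, 15, 85))
  expect_lt(sqrt(mean((sm2$predict(nc2) - bump(nc2))^2)), 0.2)
  expect_error(smooth_point_values(co[1:5, ], vp[1:5]), "at least 10")
})

test_that("ASCII-grid text rasters round-trip", {
  g <- matrix(round(runif(12), 4), 3, 4)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(g, path, xllcorner = 10, yllcorner = 20, cellsize = 30)
  rd <- read_ascii_grid(path)
  expect_equal(rd$grid, g, ignore_attr = TRUE)
  expect_equal(rd$cellsize, 30)
  g2 <- g
  g2[2, 2] <- NA
  write_ascii_grid(g2, path)
  expect_true(is.na(read_ascii_grid(path)$grid[2, 2]))
  unlink(path)
})
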