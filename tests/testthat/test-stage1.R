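# Regional back-fitting: buffers, oracle equivalence, identifiability.

test_that("buffer attachment includes neighbors within 400 km and flags
           them", {
  sites <- data.frame(
    site = c("a", "b", "c", "d"),
    x = c(100, 900, 1100, 1900), y = rep(50, 4),
    region = c("R1", "R1", "R2", "R2")
  )
  geom <- data.frame(
    region = c("R1", "R2"), xmin = c(0, 1000), xmax = c(1000, 2000),
    ymin = 0, ymax = 100
  )
  sets <- attach_buffer(sites, geom, buffer_km = 400)
  # site c (100 km past the border) joins R1's set as a buffer site
  expect_true("c" %in% sets$R1$site)
  expect_true(sets$R1$buffer[sets$R1$site == "c"])
  expect_false(sets$R1$buffer[sets$R1$site == "a"])
  # site d (900 km from R1) stays out
  expect_false("d" %in% sets$R1$site)
  # threshold is exact: 401 km out is excluded
  sites2 <- sites
  sites2$x[3] <- 1401
  expect_false("c" %in% attach_buffer(sites2, geom, 400)$R1$site)
  expect_true("c" %in% attach_buffer(sites2, geom, 401)$R1$site)
  # zero buffer partitions the sites
  s0 <- attach_buffer(sites, geom, 0)
  expect_equal(sort(c(s0$R1$site, s0$R2$site)), sort(sites$site))
  expect_error(
    attach_buffer(sites[1:2, ], geom, 400), "no sites"
  )
})

test_that("back-fitting with fixed smoothing equals the one-shot joint
           penalized solution", {
  panel <- make_small_panel(20, 3, seed = 42)
  cfg <- stage1_config(
    tol = 1e-9, max_iter = 60, lambda_z = c(z1 = 2), lambda_g = 5,
    min_month_sites = 3
  )
  bf <- backfit_region(panel, "z1", cfg, region = "A")
  expect_true(bf$converged)
  oracle <- stage1_oracle_fit(bf, panel, "z1", c(z1 = 2), 5)
  rel <- max(abs(bf$fitted - oracle)) / diff(range(panel$value))
  expect_lt(rel, 1e-6)
})

test_that("with no spatial signal the back-fit matches the joint-only
           model", {
  set.seed(20)
  panel <- make_small_panel(15, 4, seed = 20, sd_noise = 0.1)
  # remove the spatial component from the truth
  panel$value <- 2 + 0.5 * panel$z1 + rnorm(nrow(panel), 0, 0.1)
  cfg <- stage1_config(min_month_sites = 3)
  bf <- backfit_region(panel, "z1", cfg, region = "A")
  # the monthly surfaces should carry almost nothing
  g_share <- var(bf$fitted - bf$joint$fitted) / var(panel$value)
  expect_lt(g_share, 0.05)
})

test_that("monthly intercepts are mean-zero and site intercepts carry the
           level", {
  panel <- make_small_panel(20, 6, seed = 21)
  cfg <- stage1_config(min_month_sites = 3)
  bf <- backfit_region(panel, "z1", cfg, region = "A")
  expect_equal(sum(bf$alpha), 0, tolerance = 1e-8)
  expect_equal(mean(bf$sites$u), mean(panel$value), tolerance = 0.3)
  # adding a constant shifts u by that constant (the documented gauge)
  panel2 <- panel
  panel2$value <- panel$value + 3
  bf2 <- backfit_region(panel2, "z1", cfg, region = "A")
  expect_equal(bf2$sites$u, bf$sites$u + 3, tolerance = 1e-4)
  expect_equal(bf2$alpha, bf$alpha, tolerance = 1e-4)
})

test_that("with no covariates or surfaces, intercepts match the two-way
           linear-model oracle", {
  set.seed(22)
  sites <- data.frame(
    site = sprintf("s%02d", 1:12),
    x = runif(12, 0, 100), y = runif(12, 0, 100)
  )
  panel <- merge(sites, expand.grid(site = sites$site, month = 1:5))
  panel$value <- rnorm(nrow(panel), 2, 0.5)
  cfg <- stage1_config(min_month_sites = 99) # all surfaces degenerate
  expect_warning(
    bf <- backfit_region(panel, character(0), cfg, region = "A"),
    NA
  )
  # oracle: ordinary two-way fit with sum-contrast months
  panel <- panel[order(panel$site, panel$month), ]
  lm_fit <- lm(
    value ~ 0 + factor(site) + C(factor(month), "contr.sum"),
    data = panel
  )
  u_lm <- coef(lm_fit)[seq_len(12)]
  expect_equal(unname(bf$sites$u[order(bf$sites$site)]),
    unname(u_lm[order(names(u_lm))]),
    tolerance = 1e-6
  )
})

test_that("back-fitting is invariant to row ordering", {
  panel <- make_small_panel(15, 3, seed = 23)
  cfg <- stage1_config(min_month_sites = 3)
  bf1 <- backfit_region(panel, "z1", cfg, region = "A")
  set.seed(1)
  perm <- sample(nrow(panel))
  bf2 <- backfit_region(panel[perm, ], "z1", cfg, region = "A")
  expect_equal(bf1$sites$u[order(bf1$sites$site)],
    bf2$sites$u[order(bf2$sites$site)],
    tolerance = 1e-6
  )
})

test_that("buffer sites are excluded from extracted intercepts", {
  panel <- make_small_panel(15, 3, seed = 24)
  panel$buffer <- panel$site %in% c("s01", "s02")
  cfg <- stage1_config(min_month_sites = 3)
  bf <- backfit_region(panel, "z1", cfg, region = "A")
  u <- extract_site_intercepts(bf)
  expect_false(any(c("s01", "s02") %in% u$site))
  expect_equal(nrow(u), 13)
})

test_that("convergence trace shrinks and residual variances are
           nonnegative", {
  panel <- make_small_panel(20, 4, seed = 25)
  cfg <- stage1_config(min_month_sites = 3)
  bf <- backfit_region(panel, "z1", cfg, region = "A")
  expect_true(all(bf$sigma2_e >= 0))
  tr <- bf$trace
  expect_lt(tr[length(tr)], tr[2])
})

test_that("a linear covariate effect is recovered", {
  set.seed(26)
  n_s <- 60
  sites <- data.frame(
    site = sprintf("s%02d", 1:n_s),
    x = runif(n_s, 0, 500), y = runif(n_s, 0, 500)
  )
  panel <- merge(sites, expand.grid(site = sites$site, month = 1:12))
  panel$z1 <- rnorm(nrow(panel))
  panel$value <- 2 - 0.3 * panel$z1 + 0.2 * sin(panel$x / 100) +
    rnorm(nrow(panel), 0, 0.2)
  cfg <- stage1_config()
  bf <- backfit_region(panel, "z1", cfg, region = "A")
  grid <- seq(quantile(panel$z1, 0.05), quantile(panel$z1, 0.95),
    length.out = 50
  )
  fhat <- predict(bf$joint, smooth_values = list(z1 = grid))
  ftru <- -0.3 * grid - mean(-0.3 * panel$z1)
  expect_lt(sqrt(mean((fhat - ftru)^2)), 0.05)
})
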