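# Fold designs and evaluation metrics.

test_that("fold assignment partitions sites evenly and reproducibly", {
  f <- assign_folds(sprintf("s%03d", 1:100), 10, seed = 3)
  expect_equal(as.numeric(table(f$fold)), rep(10, 10))
  expect_equal(anyDuplicated(f$site), 0)
  expect_true(all(f$reserved == (f$fold == 10)))
  f2 <- assign_folds(sprintf("s%03d", 1:100), 10, seed = 3)
  expect_identical(f$fold, f2$fold)
  f3 <- assign_folds(sprintf("s%03d", 1:100), 10, seed = 4)
  expect_false(identical(f$fold, f3$fold))
  expect_error(assign_folds(letters[1:5], 10), "fewer sites")
})

test_that("evaluation-year design applies the qualification thresholds", {
  set.seed(44)
  sites <- sprintf("s%03d", 1:100)
  rows <- list()
  for (i in seq_along(sites)) {
    # 40 dense sites qualify; the rest miss one or both thresholds
    n_year <- if (i <= 40) 12 else 9
    n_hist <- if (i <= 40) 24 else 8
    rows[[i]] <- data.frame(
      site = sites[i],
      x = runif(1, 0, 1000), y = runif(1, 0, 600),
      month = c(sample(25:36, n_year), sample(1:24, n_hist))
    )
  }
  panel <- do.call(rbind, rows)
  des <- build_year2000_design(panel,
    eval_months = 25:36, seed = 7,
    min_year_obs = 10, min_total_obs = 30
  )
  expect_equal(length(des$qualifying), 0 + 40)
  # folds only over qualifying, non-withheld sites
  expect_true(all(des$folds$site %in% des$qualifying))
  expect_false(any(des$folds$site %in% des$withheld))
  # deterministic given the seed
  des2 <- build_year2000_design(panel,
    eval_months = 25:36, seed = 7,
    min_year_obs = 10, min_total_obs = 30
  )
  expect_identical(des$withheld, des2$withheld)
  expect_error(
    build_year2000_design(panel,
      eval_months = 25:36, seed = 1,
      min_year_obs = 13, min_total_obs = 30
    ),
    "no qualifying"
  )
})

test_that("CV R2 is the squared Pearson correlation (scale-free) and the
           spatial version averages by site", {
  expect_equal(cv_r2(1:10, 1:10), 1)
  expect_equal(cv_r2(1:10, 2 * (1:10) + 5), 1)
  o <- c(1, 3, 2, 5)
  p <- c(2, 3, 4, 4)
  expect_equal(cv_r2(o, p), cor(o, p)^2)
  expect_true(is.na(cv_r2(rep(1, 5), 1:5)))
  obs <- c(1, 2, 10, 11, 5, 7)
  prd <- c(2, 1, 12, 9, 4, 9)
  s <- c("a", "a", "b", "b", "c", "c")
  expect_equal(
    spatial_cv_r2(obs, prd, s),
    cor(c(1.5, 10.5, 6), c(1.5, 10.5, 6.5))^2
  )
})

test_that("NMBF/NMEF closed forms and the factor's symmetry", {
  ex <- bias_error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ex$nmbf, 0)
  expect_equal(ex$nmef, 0)
  expect_equal(ex$cvmae, 0)
  o <- runif(20, 1, 5)
  over <- bias_error_metrics(o, 2 * o)
  expect_equal(over$nmbf, 100)
  expect_equal(over$nmef, 100)
  under <- bias_error_metrics(o, o / 2)
  expect_equal(under$nmbf, -100)
  expect_equal(under$nmef, 100)
  expect_equal(under$cvmae, mean(o / 2))
})

test_that("NMEF >= |NMBF| on random data", {
  set.seed(45)
  for (i in 1:200) {
    o <- rexp(30, 1 / 10)
    m <- o * exp(rnorm(30, 0, 0.5))
    b <- bias_error_metrics(o, m)
    expect_gte(b$nmef, abs(b$nmbf) - 1e-10)
  }
})

test_that("major-axis regression matches the principal-axis oracle", {
  expect_equal(major_axis_fit(1:10, 1:10)$slope, 1)
  expect_equal(major_axis_fit(1:10, 1:10)$intercept, 0)
  # 5-point hand dataset against an explicit eigen-decomposition
  x <- c(0.1, 0.9, 1.7, 2.2, 3.3)
  y <- c(0.5, 1.4, 2.1, 3.4, 4.1)
  ma <- major_axis_fit(x, y)
  V <- cov(cbind(x, y))
  v1 <- eigen(V)$vectors[, 1]
  expect_equal(ma$slope, v1[2] / v1[1], tolerance = 1e-10)
  expect_equal(ma$intercept, mean(y) - ma$slope * mean(x),
    tolerance = 1e-10
  )
  # swapping the variables inverts the slope
  ma_sw <- major_axis_fit(y, x)
  expect_equal(ma_sw$slope, 1 / ma$slope, tolerance = 1e-10)
})

test_that("interval coverage counts inclusions and rejects bad intervals", {
  o <- c(1, 2, 3, 4)
  expect_equal(pi_coverage(o, o - 1, o + 1), 1)
  expect_equal(pi_coverage(o, o, o), 1) # degenerate but equal
  expect_equal(pi_coverage(o + 0.5, o, o), 0)
  expect_error(pi_coverage(o, o + 1, o - 1), "well-ordered")
})

test_that("stratified reports keep the bookkeeping identities", {
  set.seed(46)
  n <- 200
  cv <- data.frame(
    site = rep(sprintf("s%02d", 1:20), each = 10),
    month = rep(1:10, 20),
    observed = rexp(n, 1 / 10)
  )
  cv$predicted <- cv$observed * exp(rnorm(n, 0, 0.3))
  cv$lo95 <- cv$predicted * 0.5
  cv$hi95 <- cv$predicted * 2
  cv$exclude <- runif(n) < 0.1
  region <- rep(c("east", "west"), each = n / 2)
  rep_out <- stratified_report(cv, list(region = region))
  ov <- rep_out[rep_out$stratum_set == "overall", ]
  expect_equal(ov$n + ov$n_excluded, n)
  by_r <- rep_out[rep_out$stratum_set == "region", ]
  expect_equal(sum(by_r$n), ov$n)
  expect_equal(sum(by_r$n_excluded), ov$n_excluded)
  # identical strata give identical rows
  dup <- stratified_report(cv, list(a = region, b = region))
  ra <- dup[dup$stratum_set == "a", -1]
  rb <- dup[dup$stratum_set == "b", -1]
  expect_equal(ra, rb, ignore_attr = TRUE)
  # a tiny stratum reports missing metrics but a count
  tiny <- stratified_report(
    cv[1:4, ],
    list(g = c("u", "u", "v", "v"))
  )
  expect_true(all(is.na(tiny$cv_r2[tiny$stratum %in% c("u", "v")])))
})

test_that("residual ACF: white noise stays inside the band, AR(1) is
           detected, constants are missing", {
  set.seed(47)
  n_sites <- 30
  len <- 60
  res_w <- rnorm(n_sites * len)
  sites <- rep(seq_len(n_sites), each = len)
  months <- rep(seq_len(len), n_sites)
  aw <- residual_acf(res_w, sites, months, max_lag = 15)
  band <- 2 / sqrt(len * n_sites)
  expect_gte(mean(abs(aw$acf) <= 2 / sqrt(len)), 0.9)
  # AR(1) with rho = 0.5
  res_a <- as.numeric(replicate(n_sites,
    as.numeric(arima.sim(list(ar = 0.5), len))))
  aa <- residual_acf(res_a, sites, months, max_lag = 15)
  expect_lt(abs(aa$acf[1] - 0.5), 0.1)
  const <- residual_acf(rep(1, 40), rep(1, 40), 1:40)
  expect_true(all(is.na(const$acf)))
})
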