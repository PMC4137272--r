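# Model composition, prediction rules and error propagation.

test_that("ratio outlier removal applies the strict 1.5x rule", {
  pm25 <- c(10, 20, 32, 15, 48, 30)
  pm10h <- c(20, 20, 20, 20, 30, 20)
  rr <- remove_ratio_outliers(pm25, pm10h)
  expect_equal(rr$n_removed, 2) # 32 > 30 and 48 > 45
  expect_equal(which(!rr$keep), c(3, 5))
  # the boundary record (exactly 1.5x) is kept
  rb <- remove_ratio_outliers(30, 20)
  expect_equal(rb$n_removed, 0)
  # no violations -> identity
  expect_equal(remove_ratio_outliers(c(1, 2), c(10, 10))$n_removed, 0)
})

test_that("covariate clamping respects the training range and flags", {
  cl <- clamp_covariates(c(-5, 0.5, 2, 7), c(0, 5))
  expect_equal(cl$values, c(0, 0.5, 2, 5))
  expect_equal(cl$flag, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(clamp_covariates(1, c(0, NA)), "range")
})

test_that("delta-method native-scale conversion matches its closed form
           and a Monte-Carlo oracle", {
  nat <- predict_native(log(10), 0.05)
  expect_equal(nat$mean, 10)
  expect_equal(nat$se, 0.5)
  expect_equal(predict_native(2, 0)$se, 0)
  expect_error(predict_native(1, -0.1), "negative")
  # Monte-Carlo oracle: delta SE within 10% of the true SD for
  # log-scale SE up to 0.3
  set.seed(40)
  for (s in c(0.1, 0.2, 0.3)) {
    draws <- exp(rnorm(1e5, log(10), s))
    expect_lt(
      abs(predict_native(log(10), s)$se - sd(draws)) / sd(draws), 0.1
    )
  }
})

test_that("ratio-PM10 combination: closed forms, truncation, zero SEs", {
  cmb <- combine_ratio_pm10(0.6, 0.06, 20, 2)
  expect_equal(cmb$mean, 12)
  expect_equal(cmb$se, sqrt(0.6^2 * 4 + 400 * 0.0036))
  expect_equal(cmb$se, 1.6970563, tolerance = 1e-6)
  expect_false(cmb$ratio_truncated)
  # predicted ratio above one is used as one and flagged
  ct <- combine_ratio_pm10(1.3, 0.1, 20, 2)
  expect_true(ct$ratio_truncated)
  expect_equal(ct$mean, 20)
  expect_equal(combine_ratio_pm10(0.5, 0, 10, 0)$se, 0)
  expect_gte(combine_ratio_pm10(0.1, 0.2, 5, 4)$lo95, 0)
  expect_error(combine_ratio_pm10(-0.1, 0.1, 10, 1), "negative")
})

test_that("coarse-fraction subtraction propagates errors independently", {
  cf <- coarse_fraction(25, 3, 15, 4)
  expect_equal(cf$mean, 10)
  expect_equal(cf$se, 5) # the 3-4-5 triangle
  expect_false(cf$nonpositive)
  neg <- coarse_fraction(10, 1, 12, 1)
  expect_true(neg$nonpositive)
  expect_equal(neg$mean, -2)
  expect_equal(coarse_fraction(10, 2, 5, 2)$se, 2 * sqrt(2))
})

# one small fitted model shared by the composition tests
small_fit <- local({
  net <- generate_network(60, 2, seed = 5)
  cov <- generate_covariates(net, n_months = 12, seed = 5)
  ds <- generate_pm_panel(net, cov,
    pm_truth_config(missing_rate = 0.05), seed = 5)
  spec <- make_model_spec("pm_direct",
    tv_covariates = "temperature",
    ti_covariates = "elevation"
  )
  m <- suppressWarnings(fit_exposure_model(spec, ds))
  list(ds = ds, spec = spec, m = m)
})

test_that("the fitted model records ranges and stage structure", {
  m <- small_fit$m
  expect_s3_class(m, "exposure_model")
  expect_named(m$ti_ranges, "elevation")
  expect_true(all(c("R1", "R2") %in% names(m$stage1)))
  expect_true(all(vapply(m$stage1, function(s) s$converged, TRUE)))
  expect_equal(
    sort(names(m$tv_ranges$R1)), "temperature"
  )
})

test_that("prediction clamps out-of-range covariates and flags them", {
  m <- small_fit$m
  ds <- small_fit$ds
  nd <- ds$panel[1:4, c("site", "x", "y", "region", "month")]
  nd$elevation <- c(1e6, -100, 500, 600) # two far outside training
  nd$temperature <- c(12, 12, 1e4, 10)
  pr <- predict_exposure(m, nd, data = ds)
  expect_true(all(pr$clamped[1:3]))
  expect_true(all(is.finite(pr$native_mean)))
})

test_that("prediction outside the training months errors", {
  m <- small_fit$m
  ds <- small_fit$ds
  nd <- ds$panel[1, c("site", "x", "y", "region", "month")]
  nd$month <- 99
  expect_error(predict_exposure(m, nd, data = ds), "training window")
})

test_that("observation-level variance dominates mean-level variance", {
  m <- small_fit$m
  ds <- small_fit$ds
  nd <- ds$panel[1:50, c("site", "x", "y", "region", "month")]
  pl <- predict_log(m, nd, data = ds)
  expect_true(all(pl$se_obs >= pl$se_log))
})

test_that("serialization round-trips predictions bit-for-bit", {
  m <- small_fit$m
  ds <- small_fit$ds
  path <- tempfile(fileext = ".rds")
  save_exposure_model(m, path)
  m2 <- load_exposure_model(path)
  nd <- ds$panel[1:30, c("site", "x", "y", "region", "month")]
  expect_identical(
    predict_exposure(m, nd, data = ds),
    predict_exposure(m2, nd, data = ds)
  )
  unlink(path)
})

test_that("summary export writes the delimited tables", {
  dir <- tempfile()
  export_model_summary(small_fit$m, dir)
  expect_true(file.exists(file.path(dir, "site_intercepts.tsv")))
  terms <- read.delim(file.path(dir, "stage2_terms.tsv"))
  expect_true("space" %in% terms$term)
  unlink(dir, recursive = TRUE)
})

test_that("the ratio variant needs a PM10 model, removes outliers, and
           builds four seasonal surfaces per region", {
  ds10 <- small_fit$ds
  m10 <- small_fit$m
  dsr <- generate_ratio_panel(ds10, seed = 6, contamination = 0.02)
  specr <- make_model_spec("ratio", tv_covariates = "temperature",
    ti_covariates = "elevation")
  expect_error(fit_exposure_model(specr, dsr), "requires a fitted PM10")
  mr <- suppressWarnings(fit_exposure_model(specr, dsr,
    pm10_model = m10))
  expect_gt(mr$n_outliers_removed, 0)
  for (r in names(mr$stage1)) {
    expect_lte(sum(!vapply(mr$stage1[[r]]$g_fits, is.null, TRUE)), 4)
    expect_true("h_month" %in% names(mr$stage1[[r]]$joint$lambda))
  }
  nd <- dsr$panel[1:40, c("site", "x", "y", "region", "month")]
  pr <- predict_exposure(mr, nd, data = dsr)
  expect_true(all(pr$ratio_mean <= 1))
  expect_true(all(pr$lo95 >= 0))
  expect_true(all(pr$native_se >= 0))
})

test_that("panel text round-trip", {
  p <- small_fit$ds$panel[1:10, ]
  f <- tempfile(fileext = ".tsv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(p2$value, p$value)
  expect_equal(p2$site, p$site)
  unlink(f)
})
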