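# Shared in-code fixtures for the test suite.  Everything is generated
# deterministically; nothing is read from disk.

# a small single-region monthly panel with one linear covariate effect and
# a smooth spatial signal
make_small_panel <- function(n_sites = 20, n_months = 3, seed = 42,
                             sd_noise = 0.2) {
  set.seed(seed)
  sites <- data.frame(
    site = sprintf("s%02d", seq_len(n_sites)),
    x = runif(n_sites, 0, 100), y = runif(n_sites, 0, 100)
  )
  panel <- merge(sites, expand.grid(
    site = sites$site,
    month = seq_len(n_months)
  ))
  panel$z1 <- rnorm(nrow(panel))
  panel$value <- 2 + 0.5 * panel$z1 + 0.3 * sin(panel$x / 20) +
    rnorm(nrow(panel), 0, sd_noise)
  panel[order(panel$site, panel$month), ]
}

# direct one-shot penalized least-squares solve of the stage-1 joint model
# (site indicators + mean-zero month intercepts + covariate smooths +
# per-month centered spatial surfaces), via the augmented QR system.
# Independent of the back-fitting path: same design, solved in one shot.
stage1_oracle_fit <- function(bf, panel, z_vars, lambda_z, lambda_g) {
  panel <- panel[order(panel$site, panel$month), ]
  site_f <- factor(panel$site)
  month_f <- factor(panel$month)
  S_mat <- stats::model.matrix(~ 0 + site_f)
  M_mat <- stats::model.matrix(
    ~month_f,
    contrasts.arg = list(month_f = "contr.sum")
  )[, -1, drop = FALSE]
  P <- cbind(S_mat, M_mat)
  n <- nrow(panel)
  X <- P
  pens <- list()
  for (zv in z_vars) {
    j <- match(zv, names(bf$joint$lambda))
    tm <- bf$joint$terms[[j]]
    D <- pmgamm::basis_design(tm$basis, panel[[zv]]) %*% tm$Zc
    idx <- ncol(X) + seq_len(ncol(D))
    X <- cbind(X, D)
    pens[[length(pens) + 1]] <- list(
      idx = idx,
      S = lambda_z[[zv]] * bf$joint$pen_list[[j]]$S
    )
  }
  coords <- as.matrix(panel[, c("x", "y")])
  for (m in sort(unique(panel$month))) {
    idx_r <- which(panel$month == m)
    gf <- bf$g_fits[[as.character(m)]]
    tm <- gf$terms[[1]]
    D <- pmgamm::basis_design(tm$basis, coords[idx_r, , drop = FALSE]) %*%
      tm$Zc
    blk <- matrix(0, n, ncol(D))
    blk[idx_r, ] <- D
    idx <- ncol(X) + seq_len(ncol(D))
    X <- cbind(X, blk)
    pens[[length(pens) + 1]] <- list(
      idx = idx, S = lambda_g * gf$pen_list[[1]]$S
    )
  }
  Spen <- matrix(0, ncol(X), ncol(X))
  for (p in pens) Spen[p$idx, p$idx] <- Spen[p$idx, p$idx] + p$S
  es <- eigen((Spen + t(Spen)) / 2, symmetric = TRUE)
  pos <- es$values > max(es$values, 0) * 1e-12
  B <- t(es$vectors[, pos, drop = FALSE] *
    rep(sqrt(es$values[pos]), each = nrow(es$vectors)))
  aug <- rbind(X, B)
  rhs <- c(panel$value, numeric(nrow(B)))
  # minimum-norm least squares: the joint problem has exact gauge null
  # directions (planar patterns exchangeable between site intercepts and
  # monthly surfaces), so solve through the SVD with a rank cutoff
  sv <- svd(aug)
  pos <- sv$d > max(sv$d) * 1e-10
  cf <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
  drop(X %*% cf)
}

# small stage-2 data set with a known covariate effect and spatial bump
make_stage2_data <- function(I = 120, seed = 7, sd_noise = 0.1) {
  set.seed(seed)
  u_hat <- data.frame(
    site = sprintf("s%03d", seq_len(I)),
    x = runif(I, 0, 1000), y = runif(I, 0, 600),
    region = rep(c("A", "B"), length.out = I)
  )
  X <- data.frame(elev = runif(I, 0, 2), urban = runif(I))
  u_hat$u <- 1 + 0.5 * sin(2 * X$elev) +
    0.3 * exp(-((u_hat$x - 500)^2 + (u_hat$y - 300)^2) / (2 * 150^2)) +
    rnorm(I, 0, sd_noise)
  list(u_hat = u_hat, X = X)
}
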