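# independent ordinary-kriging oracle (simple kriging with unknown constant
# mean), assembled point by point — deliberately separate from ked_fuse
ok_oracle <- function(obs, vgm, px, py) {
  oc <- as.matrix(obs[, c("x", "y")])
  C <- vgm$psill * exp(-as.matrix(dist(oc)) / vgm$range_km)
  diag(C) <- diag(C) + vgm$nugget
  n <- nrow(oc)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  vapply(seq_along(px), function(k) {
    h <- sqrt((oc[, 1] - px[k])^2 + (oc[, 2] - py[k])^2)
    c0 <- vgm$psill * exp(-h / vgm$range_km)
    sum(solve(A, c(c0, 1))[1:n] * obs$annual_mean)
  }, numeric(1))
}

test_that("KED is exact at observation cells when the nugget is zero", {
  g <- grid_spec(7, 6)
  dr <- conc_field(g, "PM25", 1999, 10 + 0.4 * seq_len(42))
  cc <- cell_centers(g)
  idx <- c(4, 17, 29, 40)
  obs <- data.frame(x = cc$x[idx], y = cc$y[idx],
                    annual_mean = c(13, 19, 24, 28))
  vgm <- variogram_model("exponential", nugget = 0, psill = 3, range_km = 18)
  fu <- ked_fuse(obs, dr, vgm)
  expect_lt(max(abs(fu$values[idx] - obs$annual_mean)), 1e-6)
  expect_lt(max(fu$variance[idx]), 1e-8)
})

test_that("KED solves the same system as a hand-assembled GLS oracle", {
  g <- grid_spec(5, 5)
  dr <- conc_field(g, "PM25", 2005, 10 + 0.5 * seq_len(25))
  cc <- cell_centers(g)
  idx <- c(3, 12, 20)
  obs <- data.frame(x = cc$x[idx], y = cc$y[idx],
                    annual_mean = c(14, 18, 21))
  vgm <- variogram_model("exponential", nugget = 0, psill = 3, range_km = 15)
  fu <- ked_fuse(obs, dr, vgm)
  # GLS route: beta-hat by generalised least squares, then simple kriging of
  # the residuals — algebraically equivalent, assembled independently
  oc <- as.matrix(obs[, c("x", "y")])
  C <- 3 * exp(-as.matrix(dist(oc)) / 15)
  Fm <- cbind(1, dr$values[idx])
  Ci <- solve(C)
  beta <- solve(t(Fm) %*% Ci %*% Fm, t(Fm) %*% Ci %*% obs$annual_mean)
  c0 <- 3 * exp(-airsurv:::dist_mat(oc, as.matrix(cc[, c("x", "y")])) / 15)
  pred <- cbind(1, dr$values) %*% beta +
    t(c0) %*% Ci %*% (obs$annual_mean - Fm %*% beta)
  expect_lt(max(abs(fu$values - pred)), 1e-6)
})

test_that("with constant drift KED reduces to ordinary kriging", {
  g <- grid_spec(5, 5)
  dr <- conc_field(g, "PM25", 1999, rep(20, 25))
  cc <- cell_centers(g)
  idx <- c(2, 11, 23)
  obs <- data.frame(x = cc$x[idx], y = cc$y[idx],
                    annual_mean = c(15, 22, 18))
  vgm <- variogram_model("exponential", nugget = 0.5, psill = 3,
                         range_km = 15)
  fu <- ked_fuse(obs, dr, vgm)
  expect_equal(fu$values, ok_oracle(obs, vgm, cc$x, cc$y), tolerance = 1e-9)
})

test_that("kriging weights satisfy the unbiasedness constraints", {
  g <- grid_spec(8, 6)
  dr <- conc_field(g, "PM25", 1999, 12 + 0.3 * seq_len(48))
  cc <- cell_centers(g)
  set.seed(4)
  idx <- sample.int(48, 9)
  obs <- data.frame(x = cc$x[idx], y = cc$y[idx],
                    annual_mean = dr$values[idx] + rnorm(9))
  vgm <- variogram_model("exponential", nugget = 0.2, psill = 2,
                         range_km = 12)
  fu <- ked_fuse(obs, dr, vgm, return_weights = TRUE)
  lam <- attr(fu, "lambda")
  mu_obs <- attr(fu, "mu_obs")
  expect_lt(max(abs(colSums(lam) - 1)), 1e-8)
  expect_lt(max(abs(colSums(lam * mu_obs) - dr$values)), 1e-8)
})

test_that("adding a noiseless observation never increases kriging variance", {
  g <- grid_spec(6, 6)
  dr <- conc_field(g, "PM25", 1999, 15 + 0.2 * seq_len(36))
  cc <- cell_centers(g)
  vgm <- variogram_model("exponential", nugget = 0, psill = 4, range_km = 14)
  idx <- c(1, 8, 22, 30)
  obs <- data.frame(x = cc$x[idx], y = cc$y[idx],
                    annual_mean = dr$values[idx] + c(1, -1, 2, 0.5))
  v_small <- ked_fuse(obs, dr, vgm)$variance
  obs2 <- rbind(obs, data.frame(x = cc$x[15], y = cc$y[15],
                                annual_mean = dr$values[15] + 1))
  v_big <- ked_fuse(obs2, dr, vgm)$variance
  expect_true(all(v_big <= v_small + 1e-8))
})

test_that("duplicate station locations are averaged, not singular", {
  g <- grid_spec(5, 5)
  dr <- conc_field(g, "PM25", 1999, rep(20, 25))
  cc <- cell_centers(g)
  obs <- data.frame(x = cc$x[c(3, 3, 12)], y = cc$y[c(3, 3, 12)],
                    annual_mean = c(14, 18, 21))
  vgm <- variogram_model("exponential", nugget = 0, psill = 2, range_km = 10)
  fu <- ked_fuse(obs, dr, vgm)
  expect_equal(fu$values[3], 16)  # mean of the duplicates, exactness
  expect_true(all(is.finite(fu$values)))
})

test_that("zero observations fall back to the drift with infinite variance", {
  g <- grid_spec(4, 4)
  dr <- conc_field(g, "PM25", 1999, rep(18, 16))
  vgm <- variogram_model("exponential", nugget = 0, psill = 2, range_km = 10)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      annual_mean = numeric(0))
  expect_warning(fu <- ked_fuse(empty, dr, vgm), "fallback")
  expect_identical(fu$values, dr$values)
  expect_true(all(is.infinite(fu$variance)))
  expect_true(fu$fallback)
})

test_that("variogram fitting recovers generating parameters within 25%", {
  set.seed(61)
  g <- grid_spec(30, 30, cell_km = 4)
  dr <- conc_field(g, "PM25", 1999, rep(20, 900))
  true_vgm <- variogram_model("exponential", nugget = 0.5, psill = 3,
                              range_km = 20)
  nrep <- 30
  pars <- matrix(NA_real_, nrep, 3)
  for (r in seq_len(nrep)) {
    n <- 200
    xy <- cbind(runif(n, 0, 120), runif(n, 0, 120))
    C <- 3 * exp(-airsurv:::dist_mat(xy, xy) / 20)
    z <- 20 + drop(crossprod(chol(C + diag(1e-9, n)), rnorm(n))) +
      rnorm(n, 0, sqrt(0.5))
    obs <- data.frame(x = xy[, 1], y = xy[, 2], annual_mean = z)
    v <- fit_residual_variogram(obs, dr)
    pars[r, ] <- c(v$nugget, v$psill, v$range_km)
  }
  # median across replicates: the WLS range estimator is heavy-tailed on a
  # single realization, so the median is the appropriate recovery summary
  est <- apply(pars, 2, median)
  expect_lt(abs(est[1] - 0.5) / 0.5, 0.25)
  expect_lt(abs(est[2] - 3) / 3, 0.25)
  expect_lt(abs(est[3] - 20) / 20, 0.25)
})

test_that("degenerate and sparse variogram inputs take the guard paths", {
  g <- grid_spec(5, 5)
  dr <- conc_field(g, "PM25", 1999, rep(20, 25))
  cc <- cell_centers(g)
  # all residuals zero -> pure-drift, nugget and sill 0
  obs <- data.frame(x = cc$x[1:6], y = cc$y[1:6], annual_mean = rep(20, 6))
  v <- fit_residual_variogram(obs, dr)
  expect_equal(v$nugget + v$psill, 0)
  # 4 observations -> configured fallback with warning
  fb <- variogram_model("spherical", 0.1, 1, 8)
  expect_warning(v2 <- fit_residual_variogram(obs[1:4, ], dr, fallback = fb),
                 "fallback")
  expect_identical(v2, fb)
})

test_that("pure-drift worlds reproduce an affine drift exactly", {
  # zero-sill variogram: fusion reduces to a GLS fit of the affine drift link
  g <- grid_spec(6, 5)
  dr <- conc_field(g, "PM25", 1999, 10 + 0.5 * seq_len(30))
  cc <- cell_centers(g)
  idx <- c(2, 9, 17, 25, 30)
  obs <- data.frame(x = cc$x[idx], y = cc$y[idx],
                    annual_mean = 0.8 * dr$values[idx] + 3)
  v <- variogram_model("exponential", 0, 0 + 1e-300, 1)
  v$psill <- 0
  fu <- ked_fuse(obs, dr, v)
  expect_equal(fu$values, 0.8 * dr$values + 3, tolerance = 1e-9)
  expect_true(all(fu$variance == 0))
})
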