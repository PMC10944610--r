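# sparse fPCA building blocks: mean, covariance, eigensystem, scores,
# trajectories

test_that("trapezoid grid integrates constants exactly and rejects bad input", {
  g <- time_grid(-90:0)
  expect_equal(sum(g$weights), 90)
  expect_equal(fpcreg:::grid_integral(g, rep(1, 91)), 90)
  # exact for a piecewise-linear integrand
  expect_equal(fpcreg:::grid_integral(g, g$points), sum(-90:0) + 45)
  expect_error(time_grid(c(0, 0, 1)), "strictly increasing")
})

test_that("mean estimation: constants, pointwise averages, and P-spline recovery of a smooth curve", {
  # constant data give a constant mean in both modes
  df <- expand.grid(subject_id = c("A", "B"), time = -10:0)
  df$value <- 7
  ads <- analysis_dataset(as_ild(df),
                          data.frame(subject_id = c("A", "B"), outcome = 1:2))
  g <- time_grid(-10:0)
  expect_equal(estimate_mean(ads, g, "pointwise")$values, rep(7, 11))
  expect_equal(estimate_mean(ads, g, "pspline", knots = 5)$values, rep(7, 11),
               tolerance = 1e-6)

  # cross-sectional average at a day
  df2 <- data.frame(subject_id = rep(c("A", "B"), each = 2),
                    time = c(-5, -4, -5, -4), value = c(100, 100, 120, 120))
  ads2 <- analysis_dataset(as_ild(df2),
                           data.frame(subject_id = c("A", "B"), outcome = 1:2))
  mu2 <- estimate_mean(ads2, time_grid(c(-5, -4)), "pointwise")
  expect_equal(mu2$values[1], 110)
  expect_error(estimate_mean(ads2, time_grid(-6:-4), "pointwise"),
               "no neighbors")

  # P-spline fit recovers a smooth generating curve from noisy dense data
  set.seed(3)
  g91 <- time_grid(-90:0)
  mu_true <- function(t) sin(2 * pi * t / 91) + t / 50
  n <- 500
  df3 <- expand.grid(subject_id = sprintf("S%d", 1:n), time = -90:0)
  df3$value <- mu_true(df3$time) + rnorm(nrow(df3), 0, 0.5)
  ads3 <- analysis_dataset(as_ild(df3),
                           data.frame(subject_id = sprintf("S%d", 1:n),
                                      outcome = rnorm(n)))
  mu3 <- estimate_mean(ads3, g91, "pspline")
  expect_lt(max(abs(mu3$values - mu_true(g91$points))), 0.05)
})

test_that("empirical covariance equals the sample covariance on dense data", {
  study <- simulate_study(dense_noiseless_config(n = 25, seed = 2))
  fpc <- fpca_sparse(study$data, mean_method = "pointwise",
                     cov_method = "empirical", score_method = "projection")
  # independent sample covariance of the completed data matrix
  Y <- matrix(NA_real_, 25, 91)
  for (i in seq_along(study$data$subjects)) {
    rows <- study$data$obs$subject_id == study$data$subjects[i]
    Y[i, study$data$obs$time[rows] + 91] <- study$data$obs$value[rows]
  }
  S <- stats::cov(Y)
  expect_lt(max(abs(fpc$cov$surface - S)), 1e-10)
  expect_equal(fpc$noise_variance, 0)
})

test_that("smoothed covariance separates signal from measurement noise and is symmetric", {
  # smooth rank-2 signal plus i.i.d. noise of variance 25, n = 300, dense
  cfg <- sim_config(n = 300, grid = time_grid(-90:0),
                    mean_fun = function(t) 0 * t,
                    eigenvalues = c(400, 50), basis_family = "polynomial",
                    predictor_noise_sd = 5,
                    sampling = list(type = "bernoulli", prob = 1),
                    alpha = 0, beta_weights = c(1, 1),
                    outcome_noise_sd = 1, seed = 8)
  study <- simulate_study(cfg)
  ads <- center_ild(study$data, estimate_mean(study$data))
  cm <- estimate_covariance(ads)
  expect_gt(cm$noise_variance, 20)
  expect_lt(cm$noise_variance, 30)
  expect_lt(max(abs(cm$surface - t(cm$surface))), 1e-10)
  expect_error(estimate_covariance(ads, knots = 3), "at least 4")

  one_obs <- ads
  one_obs$obs <- one_obs$obs[!duplicated(one_obs$obs$subject_id), ]
  expect_error(estimate_covariance(one_obs), ">= 2 observations")
})

test_that("eigendecomposition solves the weighted problem: rank-1, isotropic, and reconstruction", {
  g <- time_grid(-90:0)
  phi <- orthonormal_basis(g, "fourier", 3)[, 2]
  G1 <- 5 * outer(phi, phi)
  cm <- structure(list(grid = g, surface = G1, noise_variance = 0),
                  class = "cov_model")
  eig <- eigendecompose_cov(cm)
  expect_lt(abs(eig$values[1] - 5), 1e-8)
  expect_lt(min(max(abs(eig$functions[, 1] - phi)),
                max(abs(eig$functions[, 1] + phi))), 1e-6)

  # isotropic case: G = 2 * W^{-1} makes W^{1/2} G W^{1/2} = 2 I
  g3 <- time_grid(0:2)
  G2 <- diag(2 / g3$weights)
  cm2 <- structure(list(grid = g3, surface = G2, noise_variance = 0),
                   class = "cov_model")
  eig2 <- eigendecompose_cov(cm2)
  expect_equal(eig2$values, rep(2, 3), tolerance = 1e-10)
  gram <- t(eig2$functions) %*% diag(g3$weights) %*% eig2$functions
  expect_lt(max(abs(gram - diag(3))), 1e-8)

  # spectral reconstruction of a random PSD surface
  set.seed(5)
  M <- matrix(rnorm(91 * 12), 91, 12)
  G3 <- tcrossprod(M)
  cm3 <- structure(list(grid = g, surface = G3, noise_variance = 0),
                   class = "cov_model")
  eig3 <- eigendecompose_cov(cm3)
  W <- diag(g$weights)
  recon <- eig3$functions %*% diag(eig3$values) %*% t(eig3$functions)
  # reconstruction identity holds in the quadrature metric
  expect_lt(norm(W %*% (recon - G3) %*% W, "F") / norm(W %*% G3 %*% W, "F"),
            1e-6)
  expect_error(eigendecompose_cov(structure(list(grid = g,
                                                 surface = G3 + 1e-3 * upper.tri(G3),
                                                 noise_variance = 0),
                                            class = "cov_model")),
               "not symmetric")
})

test_that("component selection matches a brute-force scan and is monotone in the threshold", {
  sel <- select_ncomp(c(9, 0.9, 0.1), 0.95)
  expect_equal(sel$p, 2L)
  expect_equal(select_ncomp(c(9, 0.9, 0.1), 0.90)$p, 1L)
  expect_error(select_ncomp(c(1, -0.1), 0.9), "positive")

  set.seed(11)
  for (i in 1:50) {
    ev <- sort(rexp(sample(2:12, 1)) + 1e-4, decreasing = TRUE)
    thr <- runif(1, 0.05, 1)
    brute <- min(which(vapply(seq_along(ev), function(k)
      sum(ev[1:k]) / sum(ev) >= thr - 1e-12, logical(1))))
    expect_equal(select_ncomp(ev, thr)$p, brute)
  }
  # monotone: higher threshold never selects fewer components
  ev <- c(5, 3, 1.5, 0.4, 0.1)
  ps <- vapply(seq(0.1, 1, by = 0.05), function(th) select_ncomp(ev, th)$p, 1L)
  expect_true(all(diff(ps) >= 0))
})

test_that("scree table proportions are normalized and match direct arithmetic", {
  st <- scree_table(c(3, 1))
  expect_equal(st$proportion, c(0.75, 0.25))
  expect_equal(st$cumulative, c(0.75, 1.0))
  expect_equal(scree_table(5)$proportion, 1.0)
  set.seed(2)
  st2 <- scree_table(sort(rexp(7), decreasing = TRUE) + 1e-6)
  expect_equal(st2$cumulative[7], 1, tolerance = 1e-12)
})

test_that("projection scores are exact for basis-aligned dense subjects; CE shrinks to zero on zero data", {
  g <- time_grid(-90:0)
  basis_mat <- orthonormal_basis(g, "polynomial", 2)
  eig <- structure(list(grid = g, values = c(4, 1), functions = basis_mat,
                        p = 2L, pve = 1, noise_variance = 0),
                   class = "fpca_basis")
  df <- data.frame(subject_id = "A", time = -90:0, value = 3 * basis_mat[, 1])
  ads <- fpcreg:::as_fpcr_data(df)
  ads$centered <- TRUE
  sc <- estimate_scores(ads, eig, noise_variance = 0, method = "projection")
  expect_lt(abs(sc$scores[1, 1] - 3), 1e-6)
  expect_lt(abs(sc$scores[1, 2]), 1e-6)

  # CE mode at sigma_x^2 = 0 recovers the same subject up to ridge tolerance
  sc_ce <- suppressWarnings(estimate_scores(ads, eig, noise_variance = 0,
                                            method = "ce"))
  expect_lt(abs(sc_ce$scores[1, 1] - 3), 1e-4)

  # all-zero centered values give zero scores and the prior-variance band
  df0 <- data.frame(subject_id = "Z", time = seq(-80, -10, by = 10), value = 0)
  ads0 <- fpcreg:::as_fpcr_data(df0)
  ads0$centered <- TRUE
  sc0 <- estimate_scores(ads0, eig, noise_variance = 1, method = "ce")
  expect_equal(unname(sc0$scores[1, ]), c(0, 0))
  C <- sc0$covariances[[1]]
  expect_true(all(eigen(C, symmetric = TRUE)$values > -1e-10))
  expect_true(all(diag(C) <= c(4, 1) + 1e-12))
})

test_that("conditional-expectation scores equal an independent per-subject GLS solve", {
  set.seed(9)
  g <- time_grid(-90:0)
  basis_mat <- orthonormal_basis(g, "fourier", 3)
  lam <- c(9, 4, 1)
  eig <- structure(list(grid = g, values = lam, functions = basis_mat,
                        p = 3L, pve = 1, noise_variance = 2),
                   class = "fpca_basis")
  obs <- do.call(rbind, lapply(1:20, function(i) {
    days <- sort(sample(-90:0, sample(5:40, 1)))
    data.frame(subject_id = sprintf("S%02d", i), time = days,
               value = rnorm(length(days), 0, 3))
  }))
  ads <- fpcreg:::as_fpcr_data(obs)
  ads$centered <- TRUE
  sc <- estimate_scores(ads, eig, noise_variance = 2, method = "ce")
  for (i in seq_along(sc$subjects)) {
    rows <- ads$obs$subject_id == sc$subjects[i]
    Phi <- apply(basis_mat, 2, function(f)
      approx(g$points, f, xout = ads$obs$time[rows])$y)
    y <- ads$obs$value[rows]
    # ridge-regression (Bayesian normal equations) form of the same BLUP
    A <- t(Phi) %*% Phi / 2 + diag(1 / lam)
    zeta <- solve(A, t(Phi) %*% y / 2)
    expect_lt(max(abs(sc$scores[i, ] - zeta)), 1e-8)
  }
})

test_that("recovered trajectories revert to the mean at zero scores and interpolate dense noiseless subjects", {
  study <- simulate_study(dense_noiseless_config(n = 10, seed = 4))
  fpc <- fpca_sparse(study$data, mean_method = "pointwise",
                     cov_method = "empirical", score_method = "projection",
                     npc = 2)
  s1 <- study$data$subjects[1]
  tr <- recover_trajectory(s1, fpc$scores, fpc$basis, fpc$mean)
  obs1 <- study$data$obs[study$data$obs$subject_id == s1, ]
  expect_lt(max(abs(tr$fitted[match(obs1$time, tr$time)] - obs1$value)), 1e-6)
  expect_true(all(tr$lower <= tr$fitted & tr$fitted <= tr$upper))

  # zero scores collapse onto the mean curve
  sc0 <- fpc$scores
  sc0$scores[1, ] <- 0
  tr0 <- recover_trajectory(s1, sc0, fpc$basis, fpc$mean)
  expect_equal(tr0$fitted, fpc$mean$values)
  expect_error(recover_trajectory("nobody", fpc$scores, fpc$basis, fpc$mean),
               "unknown subject")
})

test_that("dense noiseless fits match a direct weighted PCA of the data matrix", {
  study <- simulate_study(dense_noiseless_config(n = 40, seed = 6))
  fpc <- fpca_sparse(study$data, mean_method = "pointwise",
                     cov_method = "empirical", score_method = "projection",
                     npc = 2)
  g <- fpc$basis$grid
  # independent route: weighted PCA via SVD of the centered data matrix
  Y <- matrix(NA_real_, 40, 91)
  for (i in seq_along(study$data$subjects)) {
    rows <- study$data$obs$subject_id == study$data$subjects[i]
    Y[i, study$data$obs$time[rows] + 91] <- study$data$obs$value[rows]
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  sw <- sqrt(g$weights)
  sv <- svd(sweep(Yc, 2, sw, `*`) / sqrt(40 - 1))
  ev_oracle <- sv$d^2
  fn_oracle <- sweep(sv$v[, 1:2], 1, sw, `/`)
  fn_oracle <- sign_align(fn_oracle, fpc$basis$functions, g)
  expect_lt(max(abs(fpc$basis$values - ev_oracle[1:2]) / ev_oracle[1:2]), 1e-6)
  expect_lt(max(abs(fpc$basis$functions - fn_oracle)), 1e-6)
  sc_oracle <- Yc %*% (fn_oracle * g$weights)
  expect_lt(max(abs(fpc$scores$scores - sc_oracle)), 1e-6)
})

test_that("every fitted basis is quadrature-orthonormal with nonincreasing eigenvalues", {
  for (seed in 1:3) {
    study <- simulate_study(quick_config(n = 20, seed = seed))
    fpc <- fpca_sparse(study$data, grid = time_grid(-20:0), knots = 8)
    g <- fpc$basis$grid
    gram <- t(fpc$basis$functions) %*% diag(g$weights) %*% fpc$basis$functions
    expect_lt(max(abs(gram - diag(fpc$p))), 1e-8)
    expect_true(all(diff(fpc$eigen$values) <= 1e-12))
    # sign convention: nonnegative integral (or end value on ties)
    ints <- apply(fpc$basis$functions, 2, function(f) fpcreg:::grid_integral(g, f))
    ends <- fpc$basis$functions[nrow(fpc$basis$functions), ]
    expect_true(all(ints > -1e-10 | (abs(ints) <= 1e-10 & ends >= 0)))
  }
})
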