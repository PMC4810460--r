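test_that("MDL order selection recovers known ranks", {
  set.seed(1)
  T_ <- 200; V <- 1000
  mask <- array(TRUE, c(10, 10, 10))
  S <- matrix(rnorm(5 * V), 5); S <- S * (abs(S) > 1)   # strong sparse sources
  A <- matrix(rnorm(T_ * 5), T_, 5)
  r5 <- bold_run(A %*% S + matrix(rnorm(T_ * V), T_, V), mask, 2)
  expect_identical(mdl_order(list(r5)), 5L)
  noise <- bold_run(matrix(rnorm(T_ * V), T_, V), mask, 2)
  expect_lte(mdl_order(list(noise)), 1L)
  S3 <- matrix(rnorm(3 * V), 3); A3 <- matrix(rnorm(50 * 3), 50, 3)
  r3 <- bold_run(A3 %*% S3, mask, 2)
  expect_identical(mdl_order(list(r3)), 3L)
})

test_that("two-step PCA degenerates to direct PCA for one subject", {
  set.seed(2)
  mask <- array(TRUE, c(6, 6, 6))
  X <- matrix(rnorm(40 * 216), 40, 216)
  run <- bold_run(X, mask, 2)
  p <- two_step_pca(list(run), order = 5, subject_order = 5)
  Xc <- sweep(X, 2, colMeans(X))
  direct <- eigen(tcrossprod(Xc) / 216, symmetric = TRUE)$vectors[, 1:5]
  proj_direct <- crossprod(direct, Xc)
  proj_direct <- proj_direct - rowMeans(proj_direct)   # step 2 row-centers
  # same 5-dimensional voxel-space row span: principal angles ~ 0
  sv <- svd(crossprod(svd(t(p$whitened))$u, svd(t(proj_direct))$u))$d
  expect_true(all(acos(pmin(sv, 1)) < 1e-6))
})

test_that("two-step PCA captures a noiseless cohort completely", {
  coh <- simulate_cohort(noiseless_config())
  p <- two_step_pca(coh$runs, order = coh$config$k)
  expect_equal(p$group_varexp, 1, tolerance = 1e-8)
  # group subspace contains the (voxel-centered) ground-truth map row space
  Yc <- coh$truth$spatial_maps - rowMeans(coh$truth$spatial_maps)
  truth_u <- svd(t(Yc))$u
  est_u <- svd(t(p$whitened))$u
  angles <- acos(pmin(svd(crossprod(est_u, truth_u))$d, 1))
  expect_lt(max(angles) * 180 / pi, 10)
})

test_that("Infomax recovers planted supergaussian sources deterministically", {
  fx <- whitened_sources(C = 3, N = 2000, seed = 3)
  fit <- suppressWarnings(infomax_ica(fx$Xw, seed = 4))
  expect_true(all(matched_abs_cor(fit$sources, fx$S) >= 0.99))
  fit2 <- suppressWarnings(infomax_ica(fx$Xw, seed = 4))
  expect_identical(fit$sources, fit2$sources)
  # positive-skewness sign convention
  skew <- apply(fit$sources, 1, function(v) {
    v <- v - mean(v); mean(v^3) / mean(v^2)^1.5
  })
  expect_true(all(skew >= 0))
})

test_that("ICASSO is stable on identifiable sources, unstable on Gaussian ones", {
  fx <- whitened_sources(C = 3, N = 2000, seed = 3)
  ic <- icasso(fx$Xw, n_runs = 10, seed = 9)
  expect_true(all(ic$stability >= 0.9))
  expect_true(all(matched_abs_cor(ic$centrotypes, fx$S) >= 0.99))
  # Gaussian sources are not identifiable: stability drops
  set.seed(8)
  G <- matrix(rnorm(3 * 2000), 3)
  Xg <- matrix(rnorm(9), 3) %*% G
  Xgc <- Xg - rowMeans(Xg)
  e <- eigen(tcrossprod(Xgc) / 2000, symmetric = TRUE)
  icg <- suppressWarnings(icasso(diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% Xgc,
                                 n_runs = 10, seed = 9))
  expect_lt(mean(icg$stability), mean(ic$stability))
  # degenerate single run
  one <- icasso(fx$Xw, n_runs = 1, seed = 5)
  expect_equal(one$stability, rep(1, 3))
})

test_that("dual regression inverts the noiseless generative model", {
  coh <- simulate_cohort(noiseless_config())
  Y <- coh$truth$spatial_maps
  for (s in c(1, 3)) {
    dec <- dual_regression(coh$runs[[s]], Y)
    A <- coh$truth$mixing_timecourses[[s]]
    expect_lt(norm(dec$tc - A, "F") / norm(A, "F"), 1e-8)
    expect_lt(norm(dec$sc - Y, "F") / norm(Y, "F"), 1e-8)
  }
  # zero-mean orthonormal maps: spatial step reduces to projection X %*% t(Y)
  set.seed(4)
  Z <- scale(matrix(rnorm(200 * 4), 200, 4), scale = FALSE)
  Yo <- t(qr.Q(qr(Z)))                          # 4 x 200, orthonormal rows _|_ 1
  X <- matrix(rnorm(30 * 200), 30, 200)
  dec <- dual_regression(X, Yo)
  expect_equal(dec$tc, X %*% t(Yo), tolerance = 1e-8)
})

test_that("dual regression rejects rank-deficient group maps", {
  set.seed(5)
  Y <- matrix(rnorm(3 * 100), 3)
  Y <- rbind(Y, Y[1, ] + Y[2, ])
  X <- matrix(rnorm(20 * 100), 20)
  expect_error(dual_regression(X, Y), "rank deficient")
})

test_that("z-scoring standardizes, is idempotent and rejects constants", {
  set.seed(6)
  dec <- dual_regression(matrix(rnorm(30 * 50), 30), matrix(rnorm(2 * 50), 2))
  z <- zscore_decomposition(dec)
  expect_equal(rowMeans(z$sc), rep(0, 2), tolerance = 1e-10)
  expect_equal(apply(z$sc, 1, sd), rep(1, 2), tolerance = 1e-10)
  expect_equal(colMeans(z$tc), rep(0, 2), tolerance = 1e-10)
  expect_equal(apply(z$tc, 2, sd), rep(1, 2), tolerance = 1e-10)
  z2 <- zscore_decomposition(z)
  expect_equal(z2$sc, z$sc, tolerance = 1e-12)
  bad <- dec; bad$sc[1, ] <- 5
  expect_error(zscore_decomposition(bad), "component")
})

test_that("z-scored maps are invariant to positive rescaling of group maps", {
  coh <- simulate_cohort(cohort_config(n_control = 2, n_patient = 2, seed = 13))
  Y <- coh$truth$spatial_maps
  d1 <- zscore_decomposition(dual_regression(coh$runs[[1]], Y))
  d2 <- zscore_decomposition(dual_regression(coh$runs[[1]],
                                             diag(c(2, 5, 0.3, 1, 7, 0.5)) %*% Y))
  expect_equal(d1$sc, d2$sc, tolerance = 1e-8)
})

test_that("the gica fit exposes the standard modelling interface", {
  coh <- simulate_cohort(cohort_config(n_control = 3, n_patient = 3, seed = 21))
  fit <- gica(coh$runs, order = 6, n_icasso = 5, seed = 2)
  expect_s3_class(fit, "gica")
  expect_identical(dim(coef(fit)), c(6L, ncol(coh$runs[[1]]$data)))
  expect_output(print(fit), "6 components")
  sm <- summary(fit)
  expect_identical(nrow(sm), 6L)
  dec <- predict(fit, coh$runs[[1]])
  expect_s3_class(dec, "subject_decomposition")
  expect_true(dec$zscored)
  # deterministic refit
  fit2 <- gica(coh$runs, order = 6, n_icasso = 5, seed = 2)
  expect_identical(fit$maps, fit2$maps)
})
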