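test_that("covariate adjustment reduces to the plain t-test when inert", {
  set.seed(14)
  covs <- null_covariates(15, 15)
  y <- rnorm(30) + 0.8 * (covs$group == "patient")
  adj <- adjusted_group_t(y, covs, adjust = character(0))
  plain <- t.test(y[covs$group == "patient"], y[covs$group == "control"],
                  var.equal = TRUE)
  expect_equal(adj$t, unname(plain$statistic), tolerance = 1e-6)
  expect_equal(adj$p, plain$p.value, tolerance = 1e-6)
})

test_that("summary-matched reconstruction reproduces the published age t", {
  # deterministic construction with exact mean and SD per group
  make <- function(n, m, s) {
    z <- scale(seq_len(n))[, 1]    # mean 0, sd 1
    m + s * z
  }
  x <- make(20, 54.15, 8.78)
  y <- make(19, 51.58, 6.19)
  expect_equal(mean(x), 54.15); expect_equal(sd(x), 8.78)
  covs <- data.frame(group = factor(rep(c("patient", "control"), c(20, 19)),
                                    levels = c("control", "patient")))
  res <- adjusted_group_t(c(x, y), covs, adjust = character(0))
  expect_equal(res$t, 1.052, tolerance = 0.01)
})

test_that("a confound fully explaining the group difference nulls the t", {
  set.seed(15)
  covs <- null_covariates(20, 20)
  covs$age <- 50 + 10 * (covs$group == "patient") + rnorm(40, sd = 0.1)
  y <- 0.5 * covs$age + rnorm(40, sd = 0.1)
  res <- adjusted_group_t(y, covs, adjust = "age")
  unadj <- adjusted_group_t(y, covs, adjust = character(0))
  expect_lt(abs(res$t), 2)
  expect_gt(abs(unadj$t), 10)
})

test_that("adjustment is invariant to affine covariate rescaling and rejects collinearity", {
  set.seed(16)
  covs <- null_covariates(12, 12)
  y <- rnorm(24)
  r1 <- adjusted_group_t(y, covs)
  covs2 <- covs
  covs2$age <- covs2$age * 10 - 200
  covs2$education <- covs2$education / 3 + 1
  r2 <- adjusted_group_t(y, covs2)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  covs3 <- covs
  covs3$education <- 2 * covs3$age + 1
  expect_error(adjusted_group_t(y, covs3), "collinear")
})

test_that("the Monte-Carlo extent threshold matches an independent-voxel oracle", {
  skip_if_not_installed("igraph")
  mask <- array(TRUE, c(10, 10, 10))
  spec <- alphasim_spec(fwhm_mm = 0, n_sim = 1000, seed = 5)
  ks <- alphasim_threshold(mask, spec)
  # oracle: Bernoulli(voxel_p) fields, clusters via igraph components
  off <- neighbor_offsets(5, 3)
  set.seed(99)
  oracle_max <- replicate(1500, {
    supra <- which(array(runif(1000) < 0.01, c(10, 10, 10)))
    if (!length(supra)) return(0L)
    co <- arrayInd(supra, c(10, 10, 10))
    ed <- NULL
    for (i in seq_along(supra)) {
      nb <- sweep(off, 2, co[i, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= 10 & nb[, 2] >= 1 & nb[, 2] <= 10 &
        nb[, 3] >= 1 & nb[, 3] <= 10
      lin <- nb[ok, 1] + 10 * (nb[ok, 2] - 1) + 100 * (nb[ok, 3] - 1)
      j <- match(lin, supra); j <- j[!is.na(j) & j > i]
      if (length(j)) ed <- rbind(ed, cbind(i, j))
    }
    g <- igraph::make_empty_graph(length(supra), directed = FALSE)
    if (!is.null(ed)) g <- igraph::add_edges(g, t(ed))
    max(igraph::components(g)$csize)
  })
  k_oracle <- min(which(vapply(1:20, function(k) mean(oracle_max >= k),
                               numeric(1)) < 0.05))
  expect_lte(abs(ks$k - k_oracle), 1)
})

test_that("extent thresholds grow with smoothness and flag unreachable alpha", {
  mask <- array(TRUE, c(8, 8, 8))
  k0 <- alphasim_threshold(mask, alphasim_spec(fwhm_mm = 0, n_sim = 300, seed = 3))
  k6 <- alphasim_threshold(mask, alphasim_spec(fwhm_mm = 6, n_sim = 300, seed = 3))
  expect_gte(k6$k, k0$k)
  # determinism under the seed
  k0b <- alphasim_threshold(mask, alphasim_spec(fwhm_mm = 0, n_sim = 300, seed = 3))
  expect_identical(k0$max_sizes, k0b$max_sizes)
  # voxel_p -> 1: every voxel suprathreshold, max cluster fills the mask
  expect_warning(
    ks <- alphasim_threshold(mask, alphasim_spec(voxel_p = 1 - 1e-9,
                                                 n_sim = 100,
                                                 fwhm_mm = 0, seed = 2)),
    "not reachable")
  expect_false(ks$reachable)
  expect_identical(ks$k, sum(mask) + 1L)
})

test_that("voxelwise comparison recovers a planted deficit as one cluster", {
  mask <- wmfc:::ellipsoid_mask(c(12, 12, 10))
  planted <- order(-wmfc:::blob_map(c(12, 12, 10), mask, c(6, 6, 5), 1.3))[1:30]
  sim <- simulate_fc_maps(19, 20, mask, deficit_voxels = planted, d = 1.5,
                          seed = 42)
  covs <- null_covariates(19, 20, seed = 2)
  spec <- alphasim_spec(n_sim = 500, seed = 7)
  ks <- alphasim_threshold(mask, spec)
  tb <- voxelwise_group_compare(sim$maps, mask, covs, spec, k_star = ks$k)
  expect_identical(sum(tb$significant), 1L)
  sig <- tb[tb$significant, ]
  expect_lt(sig$peak_t, 0)      # patients lower
  # Dice overlap with the planted region
  lab <- attr(tb, "labels")
  clus_vox <- which(lab[mask] == sig$cluster)
  dice <- 2 * length(intersect(clus_vox, planted)) /
    (length(clus_vox) + length(planted))
  expect_gte(dice, 0.5)
  # identical maps in both groups: empty table
  flat <- matrix(rep(rnorm(sum(mask)), 39), 39, byrow = TRUE)
  tb0 <- voxelwise_group_compare(flat, mask, covs, spec, k_star = ks$k)
  expect_identical(nrow(tb0), 0L)
})

test_that("pairwise inter-network tests are antisymmetric and calibrated", {
  set.seed(18)
  covs <- null_covariates(10, 10)
  z_list <- lapply(1:20, function(i) {
    m <- matrix(rnorm(9, sd = 0.3), 3); m <- (m + t(m)) / 2; diag(m) <- NA
    dimnames(m) <- list(1:3, 1:3); m
  })
  res <- inter_fc_group_compare(z_list, covs)
  expect_identical(nrow(res), 3L)
  covs_sw <- covs
  covs_sw$group <- factor(ifelse(covs$group == "patient", "control", "patient"),
                          levels = c("control", "patient"))
  res_sw <- inter_fc_group_compare(z_list, covs_sw)
  expect_equal(res_sw$t, -res$t, tolerance = 1e-10)
  expect_equal(res_sw$p, res$p, tolerance = 1e-10)
  # type-I calibration over replicated null draws
  set.seed(19)
  hits <- replicate(150, {
    zs <- lapply(1:20, function(i) {
      m <- matrix(rnorm(9, sd = 0.3), 3); m <- (m + t(m)) / 2; diag(m) <- NA
      dimnames(m) <- list(1:3, 1:3); m
    })
    inter_fc_group_compare(zs, covs)$p[1] < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.045)
})

test_that("partial correlation matches closed forms", {
  set.seed(20)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  expect_equal(partial_corr(x, y)$r, cor(x, y), tolerance = 1e-12)
  z <- rnorm(60)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_corr(x, y, data.frame(z = z))$r, closed, tolerance = 1e-10)
  # y carried (almost) entirely by the covariate: partial r ~ 0
  y_cov <- 2 * z + rnorm(60, sd = 1e-3)
  expect_lt(abs(partial_corr(x, y_cov, data.frame(z = z))$r), 0.3)
  expect_error(partial_corr(x, rep(1, 60)), "constant")
})
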