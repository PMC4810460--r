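test_that("maximum probability labeling uses argmax with priority tie-break", {
  atlas <- list(prob = rbind(c(0.7, 0.2, 0.1),
                             c(0.4, 0.4, 0.2),
                             c(0.1, 0.2, 0.7)))
  colnames(atlas$prob) <- c("gray", "white", "csf")
  expect_message(mpm <- build_mpm(atlas), "tied")
  expect_identical(mpm, c("gray", "gray", "csf"))
  bad <- list(prob = rbind(c(0, 0, 0), c(0.5, 0.3, 0.2)))
  colnames(bad$prob) <- c("gray", "white", "csf")
  expect_error(build_mpm(bad), "all-zero")
})

test_that("components classify by highest signed tissue correlation", {
  mpm <- c(rep("gray", 40), rep("white", 30), rep("csf", 30))
  gray_ind <- as.numeric(mpm == "gray")
  cls <- classify_component(gray_ind, mpm)
  expect_identical(cls$tissue, "gray")
  expect_equal(cls$r, 1)
  # negated white indicator: white has r = -1, must NOT win
  neg_white <- -as.numeric(mpm == "white")
  cls2 <- classify_component(neg_white, mpm)
  expect_false(cls2$tissue == "white")
  # brute-force oracle: class with max signed correlation
  oracle <- c("gray", "white", "csf")[which.max(vapply(c("gray", "white", "csf"),
    function(cl) cor(neg_white, as.numeric(mpm == cl)), numeric(1)))]
  expect_identical(cls2$tissue, oracle)
  expect_error(classify_component(rep(1, 100), mpm), "constant")
})

test_that("cerebellum flag fires when the label mask beats every tissue", {
  mpm <- rep("gray", 100)
  mpm[51:100] <- "white"
  cereb <- c(rep(FALSE, 80), rep(TRUE, 20))
  blob <- as.numeric(cereb)
  cls <- classify_component(blob, mpm, cereb)
  expect_true(cls$cerebellar)
  not_cereb <- as.numeric(mpm == "gray")
  expect_false(classify_component(not_cereb, mpm, cereb)$cerebellar)
})

test_that("the activation GLM recovers slopes of the task regressor", {
  reg <- task_regressor(nback_design())
  perfect <- suppressWarnings(component_glm(reg, reg))  # lm flags the 0-residual fit
  expect_equal(perfect$beta, 1, tolerance = 1e-10)
  set.seed(9)
  orth <- residuals(lm(rnorm(126) ~ reg))
  expect_equal(component_glm(orth, reg)$beta, 0, tolerance = 1e-10)
  noisy <- 2 * reg + rnorm(126, sd = 0.1)
  expect_equal(component_glm(noisy, reg)$beta, 2, tolerance = 0.1)
  expect_error(component_glm(rnorm(10), rep(1, 10)), "constant")
})

test_that("selection keeps task-driven gray components and gates the rest", {
  report <- data.frame(component = 1:4,
                       tissue = c("gray", "gray", "white", "gray"),
                       cerebellar = c(FALSE, FALSE, FALSE, TRUE))
  set.seed(10)
  beta <- cbind(rnorm(12, 1, 0.2),   # clear effect
                rnorm(12, 0, 0.2),   # null
                rnorm(12, 3, 0.2),   # big effect but white matter
                rnorm(12, 3, 0.2))   # big effect but cerebellar
  out <- select_wm_components(report, beta)
  expect_identical(out$component[out$selected], 1L)
  expect_true(is.na(out$p_adjusted[3]) && is.na(out$p_adjusted[4]))
  # Bonferroni equivalence: adjusted p < alpha  <=>  raw p < alpha / m
  m <- 2   # gray, non-cerebellar candidates
  raw1 <- t.test(beta[, 1])$p.value
  expect_identical(out$selected[1], raw1 < 0.05 / m)
  # invariance to component ordering
  out_rev <- select_wm_components(report[4:1, ], beta)
  expect_setequal(out_rev$component[out_rev$selected],
                  out$component[out$selected])
  # invariance to positive rescaling of the betas' source TCs (scale betas)
  out_scaled <- select_wm_components(report, beta * 3)
  expect_identical(out_scaled$selected, out$selected)
  expect_error(select_wm_components(report, beta[1, , drop = FALSE]),
               "2 subjects")
})

test_that("the full selection path isolates the task components of a cohort", {
  coh <- simulate_cohort(cohort_config(seed = 7))
  fit <- gica(coh$runs, order = 6, n_icasso = 5, seed = 11)
  rep_ <- component_report(fit, coh$runs, coh$atlas, coh$config$design)
  # map fitted components onto ground truth by spatial correlation
  cc <- abs(cor(t(fit$maps), t(coh$truth$spatial_maps)))
  matched_truth <- apply(cc, 1, which.max)
  expect_setequal(matched_truth[rep_$selected], coh$config$task_components)
  # non-gray truth components were excluded
  excluded_roles <- coh$truth$roles$tissue[matched_truth[setdiff(1:6, rep_$selected)]]
  expect_true(all(excluded_roles %in% c("white", "csf", "gray")))
  expect_identical(sum(rep_$report$cerebellar), 1L)
})
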