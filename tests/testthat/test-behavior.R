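test_that("inverse efficiency score follows its defining ratio", {
  expect_equal(ies(600, 1.0), 600)
  expect_equal(ies(600, 0.8), 750)
  expect_error(ies(500, 0), "accuracy")
})

test_that("pooled t from summaries reproduces published group rows", {
  # age and fasting glucose rows of the demographic table
  age <- pooled_t(summary_stat(54.15, 8.78, 20), summary_stat(51.58, 6.19, 19))
  expect_equal(age$t, 1.052, tolerance = 0.01)
  expect_equal(age$df, 37)
  fbg <- pooled_t(summary_stat(6.96, 1.72, 20), summary_stat(4.84, 0.51, 19))
  expect_equal(fbg$t, 5.158, tolerance = 0.01)
  same <- pooled_t(summary_stat(5, 1, 10), summary_stat(5, 1, 10))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("pooled t is antisymmetric under group swap with invariant p", {
  a <- summary_stat(10, 2, 12); b <- summary_stat(8.5, 3, 15)
  ab <- pooled_t(a, b); ba <- pooled_t(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("Welch t reproduces the heteroscedastic marker row", {
  hba <- welch_t(summary_stat(7.87, 2.12, 20), summary_stat(5.55, 0.32, 19))
  expect_equal(hba$t, 4.83, tolerance = 0.01)
  expect_equal(welch_t(summary_stat(3, 1, 8), summary_stat(3, 1, 8))$t, 0)
})

test_that("Welch equals pooled t exactly for equal sizes and SDs", {
  a <- summary_stat(4.2, 1.3, 14); b <- summary_stat(3.1, 1.3, 14)
  expect_equal(welch_t(a, b)$t, pooled_t(a, b)$t)
})

test_that("2x2 chi-squared matches the closed form and its symmetries", {
  sex <- chi2_2x2(matrix(c(13, 7, 9, 10), 2, byrow = TRUE))
  expect_equal(sex$chisq, 1.232, tolerance = 0.005)
  expect_equal(sex$df, 1)
  expect_equal(chi2_2x2(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  # perfectly associated table: n(ad-bc)^2 / product of margins = n
  perf <- matrix(c(5, 0, 0, 5), 2)
  n <- sum(perf)
  expect_equal(chi2_2x2(perf)$chisq, n * (5 * 5 - 0 * 0)^2 / (5 * 5 * 5 * 5))
  expect_equal(chi2_2x2(perf)$chisq, n)
  tab <- matrix(c(13, 7, 9, 10), 2)
  expect_equal(chi2_2x2(t(tab))$chisq, chi2_2x2(tab)$chisq)
  expect_equal(chi2_2x2(tab[2:1, ])$chisq, chi2_2x2(tab)$chisq)
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("Mann-Whitney U handles separation, identity and small samples", {
  res <- mann_whitney(11:15, 1:5)
  expect_equal(res$U, 25)          # n1 * n2, complete separation
  same <- mann_whitney(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$p, 1, tolerance = 1e-9)
  # exhaustive permutation oracle at n1 = n2 = 5
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0); y <- c(0.8, 1.9, 2.2, 3.0, 3.3)
  obs <- mann_whitney(x, y)
  pool <- c(x, y); n1 <- 5
  mu <- n1 * (length(pool) - n1) / 2
  us <- apply(utils::combn(length(pool), n1), 2, function(ix) {
    r <- rank(pool)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  })
  p_exact <- mean(abs(us - mu) >= abs(obs$U - mu) - 1e-9)
  expect_lt(abs(obs$p - p_exact), 0.08)
  expect_equal(sign(obs$z), sign(obs$U - mu))
})

test_that("normality gate routes known distributions correctly", {
  set.seed(42)
  expect_identical(normality_gate(rnorm(200)), "normal")
  expect_identical(normality_gate(rexp(200)), "non-normal")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_warning(out <- normality_gate(rep(1, 10)), "constant")
  expect_identical(out, "non-normal")
})

test_that("Cohen's d matches the pooled-SD formula", {
  a <- summary_stat(5, 1, 10); b <- summary_stat(5, 1, 10)
  expect_equal(cohens_d(a, b), 0)
  expect_equal(abs(cohens_d(summary_stat(6, 1, 10), summary_stat(5, 1, 10))), 1)
  a <- summary_stat(7.87, 2.12, 20); b <- summary_stat(5.55, 0.32, 19)
  sp <- sqrt((19 * 2.12^2 + 18 * 0.32^2) / 37)
  expect_equal(cohens_d(a, b), (7.87 - 5.55) / sp)
})

test_that("behavioral metrics score one condition with correct-only RTs", {
  rec <- data.frame(condition = rep(c("0-back", "1-back"), each = 4),
                    correct = c(TRUE, TRUE, TRUE, TRUE,
                                TRUE, TRUE, FALSE, FALSE),
                    rt_ms = c(400, 420, 380, 400, 600, 640, 900, 950))
  m <- behavior_metrics(rec, "1-back")
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$mean_rt, 620)
  expect_equal(m$ies, 1240)
  m_all <- behavior_metrics(rec, "1-back", correct_only = FALSE)
  expect_equal(m_all$mean_rt, mean(c(600, 640, 900, 950)))
})

test_that("the group comparison table routes variables by normality", {
  set.seed(7)
  df <- data.frame(group = rep(c("a", "b"), each = 40),
                   normal_var = c(rnorm(40, 1), rnorm(40, 1.5)),
                   skewed_var = rexp(80, 1))
  tab <- compare_groups(df, "group", c("normal_var", "skewed_var"))
  expect_identical(tab$test[tab$variable == "normal_var"], "pooled t")
  expect_identical(tab$test[tab$variable == "skewed_var"], "Mann-Whitney")
  expect_true(all(is.finite(tab$statistic)))
})
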