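#' Inverse efficiency score
#'
#' IES corrects mean reaction time for accuracy: mean RT divided by the
#' accuracy ratio, in the RT's units (ms here). It penalizes fast-but-sloppy
#' responding and is undefined at zero accuracy.
#'
#' @param mean_rt mean reaction time (ms).
#' @param accuracy accuracy ratio in (0, 1].
#' @return IES in ms.
#' @examples
#' ies(600, 0.8)  # 750
#' @export
ies <- function(mean_rt, accuracy) {
  stopifnot_scalar(mean_rt, "mean_rt")
  stopifnot_scalar(accuracy, "accuracy")
  if (accuracy <= 0) stop("IES undefined: accuracy must be > 0")
  if (accuracy > 1) stop("accuracy must be <= 1")
  mean_rt / accuracy
}

#' Group summary statistic
#'
#' Mean/SD/n triplet for one group, the unit the summary-level tests operate
#' on (so published tables can be re-tested without raw data).
#'
#' @param mean,sd,n group mean, standard deviation (>= 0) and size (>= 2).
#' @param group optional group label.
#' @return An object of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n, group = NA_character_) {
  stopifnot_scalar(mean, "mean")
  stopifnot_scalar(sd, "sd")
  if (sd < 0) stop("`sd` must be >= 0")
  if (n < 2 || n != round(n)) stop("`n` must be an integer >= 2")
  structure(list(group = group, n = as.integer(n), mean = mean, sd = sd),
            class = "summary_stat")
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's equal-variance t computed from group means, SDs and sizes,
#' with df = n1 + n2 - 2 and a two-sided p-value.
#'
#' @param a,b `summary_stat` objects.
#' @return list with `t`, `df`, `p`.
#' @export
pooled_t <- function(a, b) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: t is infinite")
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p = 0))
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch's unequal-variance t test from summary statistics
#'
#' Unpooled t with Satterthwaite degrees of freedom; needed where group
#' variances differ by an order of magnitude (e.g. a clinical marker that is
#' tightly regulated in controls but variable in patients).
#'
#' @inheritParams pooled_t
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    warning("zero variances with unequal means: t is infinite")
    return(list(t = sign(a$mean - b$mean) * Inf, df = a$n + b$n - 2, p = 0))
  }
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference using the pooled SD.
#'
#' @inheritParams pooled_t
#' @return numeric d.
#' @export
cohens_d <- function(a, b) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (sp == 0) stop("Cohen's d undefined: pooled SD is zero")
  (a$mean - b$mean) / sp
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction: n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#' Used for the sex-by-group contingency comparison.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `chisq`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("`tab` must be 2x2")
  if (any(tab < 0) || sum(tab) == 0) stop("counts must be >= 0 with positive total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared undefined: a margin of the table is zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum U statistic with the tie-corrected normal approximation, the
#' route taken for non-normally distributed variables. `U` counts pairs where
#' an `x` exceeds a `y` (ties counted 1/2).
#'
#' @param x,y numeric samples.
#' @return list with `U`, `z`, `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)   # continuity correction
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Normality gate for choosing the two-sample test
#'
#' Shapiro-Wilk at alpha = 0.05: p >= alpha routes the variable to the
#' t-test, otherwise to Mann-Whitney. A constant vector is routed
#' non-normal with a warning (Shapiro-Wilk is undefined there).
#'
#' @param values numeric vector, n >= 3.
#' @param alpha gate level.
#' @return `"normal"` or `"non-normal"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("normality gate needs n >= 3")
  if (stats::sd(values) == 0) {
    warning("constant sample: routed to the non-normal branch")
    return("non-normal")
  }
  if (stats::shapiro.test(values)$p.value >= alpha) "normal" else "non-normal"
}

#' Per-subject working-memory performance metrics
#'
#' Accuracy ratio, mean RT and IES for one condition of a behavioral record.
#' Mean RT is computed over correct trials only by default (the usual
#' convention for speed measures).
#'
#' @param record a behavioral record: data.frame with columns `condition`,
#'   `correct` (logical) and `rt_ms`.
#' @param condition condition to score (default the memory condition).
#' @param correct_only restrict mean RT to correct trials.
#' @return list with `accuracy`, `mean_rt`, `ies`, `n_trials`.
#' @export
behavior_metrics <- function(record, condition = "1-back", correct_only = TRUE) {
  record <- as.data.frame(record)
  rows <- record[record$condition == condition, , drop = FALSE]
  if (nrow(rows) == 0) stop("no trials for condition '", condition, "'")
  acc <- mean(rows$correct)
  rt_rows <- if (correct_only) rows[rows$correct, , drop = FALSE] else rows
  mean_rt <- if (nrow(rt_rows)) mean(rt_rows$rt_ms) else NA_real_
  list(accuracy = acc, mean_rt = mean_rt,
       ies = if (acc > 0 && is.finite(mean_rt)) ies(mean_rt, acc) else NA_real_,
       n_trials = nrow(rows))
}

#' Group comparison table for demographic and clinical variables
#'
#' For each numeric variable both groups are gated through Shapiro-Wilk:
#' normal variables are compared with the pooled t-test, the rest with
#' Mann-Whitney. Cohen's d is reported for all rows.
#'
#' @param data data.frame of per-subject values.
#' @param group name of the two-level group column.
#' @param vars character vector of numeric columns to compare.
#' @param alpha Shapiro-Wilk gate level.
#' @return data.frame with one row per variable: group means/SDs, the test
#'   used, its statistic, p-value and Cohen's d.
#' @export
compare_groups <- function(data, group = "group", vars, alpha = 0.05) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("`group` must have exactly two levels")
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x <- data[[v]][g == lv[1]]
    y <- data[[v]][g == lv[2]]
    ss <- list(summary_stat(mean(x), stats::sd(x), length(x), lv[1]),
               summary_stat(mean(y), stats::sd(y), length(y), lv[2]))
    gate <- tryCatch({
      if (normality_gate(x, alpha) == "normal" &&
          normality_gate(y, alpha) == "normal") "normal" else "non-normal"
    }, warning = function(w) "non-normal")
    if (gate == "normal") {
      res <- pooled_t(ss[[1]], ss[[2]])
      stat <- res$t; test <- "pooled t"; p <- res$p
    } else {
      res <- mann_whitney(x, y)
      stat <- res$z; test <- "Mann-Whitney"; p <- res$p
    }
    data.frame(variable = v,
               mean_1 = ss[[1]]$mean, sd_1 = ss[[1]]$sd,
               mean_2 = ss[[2]]$mean, sd_2 = ss[[2]]$sd,
               test = test, statistic = stat, p = p,
               d = cohens_d(ss[[1]], ss[[2]]))
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}
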