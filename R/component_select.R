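# Component selection: tissue classification via maximum probability maps,
# cerebellum exclusion, and task-relatedness testing of component timecourses.

#' Maximum probability tissue labels
#'
#' Assigns each in-mask voxel the tissue class with the highest prior
#' probability. Ties break deterministically by the fixed priority
#' gray > white > csf (and are reported via a message).
#'
#' @param atlas a tissue atlas: list with `prob`, a voxel x class matrix with
#'   columns `gray`, `white`, `csf`.
#' @return character vector of per-voxel labels.
#' @export
build_mpm <- function(atlas) {
  prob <- atlas$prob
  classes <- c("gray", "white", "csf")
  if (!all(classes %in% colnames(prob)))
    stop("atlas must provide gray, white and csf probabilities")
  prob <- prob[, classes, drop = FALSE]
  if (any(rowSums(prob) == 0))
    stop("voxel(s) with all-zero tissue probabilities")
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  ties <- apply(prob, 1, function(p) sum(p == max(p)) > 1)
  if (any(ties))
    message(sum(ties), " voxel(s) had tied probabilities; broken by class priority")
  classes[max.col(prob, ties.method = "first")]
}

#' Classify a component by tissue
#'
#' Correlates the component's voxel vector with each tissue's binary
#' indicator from the maximum probability map; the class with the highest
#' signed correlation wins. If a cerebellum label mask is supplied and beats
#' every tissue correlation, the component is flagged cerebellar.
#'
#' @param map numeric spatial map over in-mask voxels.
#' @param mpm per-voxel tissue labels from [build_mpm()].
#' @param cerebellum optional logical per-voxel cerebellum mask.
#' @return list: `tissue`, `r` (winning correlation), `cerebellar`,
#'   `r_cerebellum`.
#' @export
classify_component <- function(map, mpm, cerebellum = NULL) {
  if (stats::sd(map) == 0) stop("constant component map cannot be classified")
  classes <- c("gray", "white", "csf")
  rs <- vapply(classes, function(cl) {
    ind <- as.numeric(mpm == cl)
    if (stats::sd(ind) == 0) -Inf else stats::cor(map, ind)
  }, numeric(1))
  best <- which.max(rs)
  r_cer <- if (!is.null(cerebellum) && any(cerebellum) && !all(cerebellum))
    stats::cor(map, as.numeric(cerebellum)) else -Inf
  list(tissue = classes[best], r = unname(rs[best]),
       cerebellar = is.finite(r_cer) && r_cer > max(rs),
       r_cerebellum = if (is.finite(r_cer)) r_cer else NA_real_)
}

#' Task-activation GLM for one component timecourse
#'
#' Ordinary least squares of a subject's temporal component on an intercept
#' and the HRF-convolved task contrast regressor; the slope is the
#' component's activation in response to memory load.
#'
#' @param tc numeric temporal component.
#' @param regressor task contrast regressor, same length.
#' @return list: `beta` (contrast slope), `se`, `t`.
#' @export
component_glm <- function(tc, regressor) {
  if (length(tc) != length(regressor)) stop("tc and regressor lengths differ")
  if (stats::sd(regressor) == 0) stop("constant task regressor")
  fit <- stats::lm(tc ~ regressor)
  co <- summary(fit)$coefficients
  list(beta = unname(co["regressor", "Estimate"]),
       se = unname(co["regressor", "Std. Error"]),
       t = unname(co["regressor", "t value"]))
}

#' Select working-memory-related components
#'
#' Gray-matter, non-cerebellar components whose across-subject mean
#' activation differs from zero in a second-level one-sample t-test at
#' Bonferroni-adjusted p < alpha (adjusted over the candidate components
#' that pass the tissue gate).
#'
#' @param report data.frame with columns `component`, `tissue`, `cerebellar`
#'   (as produced by [component_report()]).
#' @param beta per-subject activation matrix, subject x component.
#' @param alpha significance level after Bonferroni adjustment.
#' @return the report with columns `t`, `p_adjusted`, `selected` added.
#' @export
select_wm_components <- function(report, beta, alpha = 0.05) {
  beta <- as.matrix(beta)
  if (nrow(beta) < 2) stop("need at least 2 subjects for the group-level test")
  candidates <- which(report$tissue == "gray" & !report$cerebellar)
  tt <- rep(NA_real_, nrow(report))
  praw <- rep(NA_real_, nrow(report))
  for (j in candidates) {
    res <- stats::t.test(beta[, report$component[j]])
    tt[j] <- unname(res$statistic)
    praw[j] <- res$p.value
  }
  padj <- rep(NA_real_, nrow(report))
  padj[candidates] <- stats::p.adjust(praw[candidates], method = "bonferroni")
  report$t <- tt
  report$p_adjusted <- padj
  report$selected <- !is.na(padj) & padj < alpha
  report
}

#' Per-component classification and activation report
#'
#' Runs the full component-selection path on a fitted group ICA: classifies
#' every component against the tissue atlas, estimates each subject's
#' activation slope from the back-reconstructed timecourses, and applies the
#' group-level selection test.
#'
#' @param fit a [gica()] fit.
#' @param runs list of [bold_run()] used to back-reconstruct subjects.
#' @param atlas tissue atlas (e.g. the synthetic cohort's).
#' @param design a [task_design()].
#' @param alpha Bonferroni-adjusted selection level.
#' @return list: `report` (one row per component: tissue, correlation,
#'   cerebellar flag, group t, adjusted p, selected), `beta`
#'   (subject x component activation matrix), `selected` (component ids).
#' @export
component_report <- function(fit, runs, atlas, design, alpha = 0.05) {
  stopifnot(inherits(fit, "gica"))
  runs <- as_run_list(runs)
  mpm <- build_mpm(atlas)
  cls <- lapply(seq_len(fit$order), function(i)
    classify_component(fit$maps[i, ], mpm, atlas$cerebellum))
  report <- data.frame(component = seq_len(fit$order),
                       tissue = vapply(cls, `[[`, character(1), "tissue"),
                       r = vapply(cls, `[[`, numeric(1), "r"),
                       cerebellar = vapply(cls, `[[`, logical(1), "cerebellar"))
  regressor <- task_regressor(design)
  beta <- t(vapply(runs, function(r) {
    dec <- zscore_decomposition(dual_regression(r, fit$maps))
    vapply(seq_len(fit$order), function(j)
      component_glm(dec$tc[, j], regressor)$beta, numeric(1))
  }, numeric(fit$order)))
  report <- select_wm_components(report, beta, alpha)
  list(report = report, beta = beta,
       selected = report$component[report$selected])
}
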