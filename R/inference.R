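# Group inference: covariate-adjusted two-sample tests, Monte-Carlo
# cluster-extent correction (AlphaSim-style), voxelwise comparison with
# cluster reporting, pairwise network tests, and partial correlation.

#' Covariate-adjusted two-sample t-test
#'
#' Fits `value ~ group + covariates` by ordinary least squares and reports
#' the group coefficient's t statistic (patient minus control under the
#' default level order), its two-sided p-value, and Cohen's d computed
#' between the groups' covariate-adjusted residuals.
#'
#' @param values numeric per-subject outcome.
#' @param covariates data.frame with a two-level `group` column and the
#'   adjustment variables.
#' @param adjust names of adjustment columns (default age, gender, education;
#'   use `character(0)` for an unadjusted test).
#' @return list: `t`, `df`, `p`, `d`.
#' @export
adjusted_group_t <- function(values, covariates,
                             adjust = c("age", "gender", "education")) {
  covariates <- as.data.frame(covariates)
  g <- factor(covariates$group)
  if (nlevels(g) != 2) stop("`group` must have exactly two levels")
  X <- cbind(1, as.numeric(g) - 1)
  for (v in adjust) X <- cbind(X, as.numeric(covariates[[v]]))
  colnames(X) <- c("(Intercept)", "group", adjust)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop("collinear covariates: ", paste(dep, collapse = ", "))
  }
  n <- length(values)
  if (n < length(adjust) + 3) stop("too few subjects for the adjustment model")
  fit <- stats::lm.fit(X, values)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * XtXinv[2, 2])
  t_ <- unname(fit$coefficients["group"]) / se
  # effect size on covariate-adjusted values (group left out of the model)
  Xa <- X[, -2, drop = FALSE]
  res <- stats::lm.fit(Xa, values)$residuals
  d <- cohens_d(summary_stat(mean(res[g == levels(g)[2]]),
                             stats::sd(res[g == levels(g)[2]]),
                             sum(g == levels(g)[2])),
                summary_stat(mean(res[g == levels(g)[1]]),
                             stats::sd(res[g == levels(g)[1]]),
                             sum(g == levels(g)[1])))
  list(t = unname(t_), df = df, p = 2 * stats::pt(-abs(t_), df), d = d)
}

#' Monte-Carlo cluster-extent correction specification
#'
#' Parameters of the AlphaSim-style simulation: per-voxel threshold,
#' simulation count, assumed smoothness, cluster connection radius, voxel
#' size and the corrected alpha.
#'
#' @param voxel_p uncorrected per-voxel two-sided p threshold.
#' @param n_sim number of Monte-Carlo noise fields.
#' @param fwhm_mm Gaussian smoothness of the noise, mm FWHM.
#' @param radius_mm cluster connection radius, mm.
#' @param voxel_mm voxel edge length, mm.
#' @param alpha corrected cluster-level alpha.
#' @param df degrees of freedom of the statistic field the threshold will be
#'   applied to; `NULL` simulates plain Gaussian fields (the classic
#'   convention, which is anticonservative for low-df t maps), a number
#'   simulates matched t fields (a one-sample t across `df + 1` independent
#'   smooth Gaussian fields).
#' @param seed integer seed.
#' @return list of class `alphasim_spec`.
#' @export
alphasim_spec <- function(voxel_p = 0.01, n_sim = 1000L, fwhm_mm = 6,
                          radius_mm = 5, voxel_mm = 3, alpha = 0.05,
                          df = NULL, seed = 1L) {
  if (voxel_p <= 0 || voxel_p >= 1) stop("`voxel_p` must be in (0, 1)")
  if (n_sim < 100) stop("`n_sim` must be >= 100")
  if (fwhm_mm < 0 || radius_mm <= 0 || voxel_mm <= 0 || alpha <= 0)
    stop("spec parameters must be positive")
  if (!is.null(df) && (df < 2 || df != round(df)))
    stop("`df` must be an integer >= 2")
  structure(list(voxel_p = voxel_p, n_sim = as.integer(n_sim),
                 fwhm_mm = fwhm_mm, radius_mm = radius_mm,
                 voxel_mm = voxel_mm, alpha = alpha, df = df,
                 seed = as.integer(seed)),
            class = "alphasim_spec")
}

#' Monte-Carlo cluster-extent threshold
#'
#' For each iteration a noise field is generated on the grid, smoothed to the
#' specified FWHM, re-standardized within the mask (so the voxel threshold
#' applies to unit-scale values), thresholded two-sided at `voxel_p`, and its
#' largest cluster under the radius-implied neighbor set recorded. The
#' threshold k* is the smallest extent whose exceedance frequency falls below
#' `alpha`. With `df` set in the spec the noise is a matched t field (a
#' one-sample t across `df + 1` smoothed Gaussian fields) and the voxel
#' threshold is the t quantile; otherwise a Gaussian field and the normal
#' quantile.
#'
#' @param mask logical 3-D array.
#' @param spec an [alphasim_spec()].
#' @return list: `k` (minimum significant extent), `reachable` (FALSE when
#'   no extent attains alpha, in which case `k` is the mask size plus one),
#'   `max_sizes` (the simulated maxima).
#' @export
alphasim_threshold <- function(mask, spec = alphasim_spec()) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!any(mask)) stop("empty mask")
  offsets <- neighbor_offsets(spec$radius_mm, spec$voxel_mm)
  thr <- if (is.null(spec$df)) stats::qnorm(1 - spec$voxel_p / 2)
  else stats::qt(1 - spec$voxel_p / 2, spec$df)
  grid <- dim(mask)
  smooth_unit <- function() {
    field <- array(stats::rnorm(prod(grid)), grid)
    if (spec$fwhm_mm > 0)
      field <- gaussian_smooth3d(field, spec$fwhm_mm, spec$voxel_mm)
    v <- field[mask]
    (v - mean(v)) / stats::sd(v)
  }
  max_sizes <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_sim), function(i) {
      vals <- if (is.null(spec$df)) smooth_unit()
      else {
        # matched t field: one-sample t across df + 1 independent fields
        m <- spec$df + 1L
        fl <- vapply(seq_len(m), function(j) smooth_unit(), numeric(sum(mask)))
        mu <- rowMeans(fl)
        sdv <- sqrt(rowSums((fl - mu)^2) / spec$df)
        mu / (sdv / sqrt(m))
      }
      supra <- array(FALSE, grid)
      supra[mask] <- abs(vals) > thr
      sizes <- label_clusters(supra, offsets)$sizes
      if (length(sizes)) sizes[1] else 0L
    }, integer(1))
  })
  V <- sum(mask)
  k <- NA_integer_
  for (cand in seq_len(V)) {
    if (mean(max_sizes >= cand) < spec$alpha) { k <- cand; break }
  }
  reachable <- !is.na(k)
  if (!reachable) {
    warning("corrected alpha not reachable: largest clusters fill the mask")
    k <- V + 1L
  }
  list(k = k, reachable = reachable, max_sizes = max_sizes)
}

# vectorized covariate-adjusted group t over map columns
voxelwise_t <- function(maps, covariates, adjust = c("age", "gender", "education")) {
  g <- factor(covariates$group)
  X <- cbind(1, as.numeric(g) - 1)
  for (v in adjust) X <- cbind(X, as.numeric(covariates[[v]]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates in the voxelwise model")
  B <- qr.coef(qx, maps)
  res <- maps - X %*% B
  df <- nrow(maps) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  t_ <- B[2, ] / sqrt(pmax(sigma2, .Machine$double.eps) * XtXinv[2, 2])
  list(t = t_, df = df)
}

#' Voxelwise group comparison with cluster-extent correction
#'
#' Covariate-adjusted two-sample t at every in-mask voxel, two-sided
#' thresholding at the spec's `voxel_p`, cluster labeling under the
#' radius-implied neighbor set, and reporting of every cluster with its
#' extent, peak statistic and corrected-significance flag (extent >= k*).
#'
#' @param maps subject x voxel matrix (columns ordered as `which(mask)`).
#' @param mask logical 3-D array.
#' @param covariates data.frame with `group` and adjustment columns.
#' @param spec an [alphasim_spec()].
#' @param k_star precomputed cluster-extent threshold; `NULL` recomputes it
#'   for this mask via [alphasim_threshold()].
#' @param adjust adjustment variable names.
#' @return data.frame of class `cluster_table`: one row per cluster (possibly
#'   zero rows) with `cluster`, `extent`, `peak_t`, `peak_x/y/z` (grid
#'   indices), `significant`. Attributes: `t_map`, `k_star`, `df`.
#' @export
voxelwise_group_compare <- function(maps, mask, covariates,
                                    spec = alphasim_spec(), k_star = NULL,
                                    adjust = c("age", "gender", "education")) {
  maps <- as.matrix(maps)
  stopifnot(sum(mask) == ncol(maps))
  empty <- data.frame(cluster = integer(0), extent = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      significant = logical(0))
  class(empty) <- c("cluster_table", class(empty))
  if (!any(mask)) { warning("empty mask"); return(empty) }
  g <- table(covariates$group)
  if (length(g) != 2 || any(g < 2)) stop("need at least 2 subjects per group")
  vt <- voxelwise_t(maps, covariates, adjust)
  if (is.null(k_star)) k_star <- alphasim_threshold(mask, spec)$k
  tthr <- stats::qt(1 - spec$voxel_p / 2, vt$df)
  supra <- array(FALSE, dim(mask))
  supra[mask] <- abs(vt$t) > tthr
  lab <- label_clusters(supra, neighbor_offsets(spec$radius_mm, spec$voxel_mm))
  t_vol <- array(0, dim(mask)); t_vol[mask] <- vt$t
  rows <- lapply(seq_along(lab$sizes), function(ci) {
    vox <- which(lab$labels == ci)
    peak <- vox[which.max(abs(t_vol[vox]))]
    co <- arrayInd(peak, dim(mask))
    data.frame(cluster = ci, extent = lab$sizes[ci], peak_t = t_vol[peak],
               peak_x = co[1], peak_y = co[2], peak_z = co[3],
               significant = lab$sizes[ci] >= k_star)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("cluster_table", class(out))
  attr(out, "t_map") <- vt$t
  attr(out, "labels") <- lab$labels
  attr(out, "k_star") <- k_star
  attr(out, "df") <- vt$df
  out
}

#' Pairwise inter-network group comparison
#'
#' Covariate-adjusted two-sample t-test of each component pair's Fisher-z
#' connectivity, reported uncorrected with Cohen's d.
#'
#' @param z_list list of per-subject `inter_fc` matrices (same dimnames).
#' @param covariates data.frame with `group` and adjustment columns.
#' @param adjust adjustment variable names.
#' @return data.frame: `comp_i`, `comp_j`, `t`, `p`, `d`.
#' @export
inter_fc_group_compare <- function(z_list, covariates,
                                   adjust = c("age", "gender", "education")) {
  stopifnot(length(z_list) >= 4)
  comps <- rownames(z_list[[1]])
  k <- length(comps)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vals <- vapply(z_list, function(m) m[i, j], numeric(1))
    res <- adjusted_group_t(vals, covariates, adjust)
    rows[[length(rows) + 1L]] <-
      data.frame(comp_i = comps[i], comp_j = comps[j],
                 t = res$t, p = res$p, d = res$d)
  }
  do.call(rbind, rows)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariates (with intercept); the p-value uses the t transform with
#' df = n - ncov - 2. With no covariates this is the plain correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of control variables (may have
#'   zero columns).
#' @return list: `r`, `df`, `p`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  ncov <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n < ncov + 3) stop("too few observations")
  if (ncov > 0) {
    Z <- cbind(1, as.matrix(as.data.frame(covariates)))
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant residuals: partial correlation undefined")
  r <- stats::cor(x, y)
  df <- n - ncov - 2
  t_ <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t_), df))
}
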