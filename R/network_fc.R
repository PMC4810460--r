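# Condition-specific functional connectivity: intra-network FC is the
# z-scored subject spatial map from dual regression restricted to the memory
# condition's volumes; inter-network FC is the Fisher-z-transformed Pearson
# correlation between temporal components.

#' Condition-specific dual regression
#'
#' Restricts a run to the volumes of one condition (shifted by the
#' hemodynamic delay and concatenated contiguously), re-runs dual regression
#' on the restricted data, and z-scores the resulting decomposition. The
#' spatial maps of this decomposition are the subject's intra-network FC
#' maps for that condition.
#'
#' @param run a [bold_run()].
#' @param maps group spatial maps, component x voxel.
#' @param design a [task_design()].
#' @param condition condition whose volumes are retained.
#' @param delay_volumes hemodynamic delay in volumes (default 3, i.e. 6 s at
#'   TR = 2 s).
#' @return a z-scored `subject_decomposition` with attribute `volumes` (the
#'   retained volume indices).
#' @export
condition_decomposition <- function(run, maps, design, condition = "1-back",
                                    delay_volumes = 3L) {
  stopifnot(inherits(run, "bold_run"))
  idx <- condition_volumes(design, condition, delay_volumes)
  if (length(idx) == 0) stop("no volumes retained for condition '", condition, "'")
  if (length(idx) < nrow(as.matrix(maps)))
    stop("fewer retained volumes than components")
  dec <- zscore_decomposition(dual_regression(subset_volumes(run, idx), maps))
  attr(dec, "volumes") <- idx
  attr(dec, "condition") <- condition
  dec
}

#' Fisher r-to-z transform
#'
#' @param r correlation(s) with |r| < 1.
#' @return atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("Fisher z undefined at |r| >= 1")
  atanh(r)
}

#' Inter-network functional connectivity matrix
#'
#' Fisher-z-transformed Pearson correlations between the temporal components
#' of every selected component pair. The diagonal is stored as NA (atanh(1)
#' is undefined).
#'
#' @param dec a `subject_decomposition`.
#' @param selected component indices to include (>= 2).
#' @return symmetric matrix of class `inter_fc` with NA diagonal, dimnames
#'   the selected components.
#' @export
inter_network_fc <- function(dec, selected) {
  stopifnot(inherits(dec, "subject_decomposition"))
  selected <- as.integer(selected)
  if (length(selected) < 2) stop("need at least 2 selected components")
  tc <- dec$tc[, selected, drop = FALSE]
  sds <- apply(tc, 2, stats::sd)
  if (any(sds == 0))
    stop("constant temporal component(s): ",
         paste(selected[sds == 0], collapse = ", "))
  r <- stats::cor(tc)
  off <- abs(r) >= 1 & row(r) != col(r)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("perfectly correlated pair (%d, %d): Fisher z infinite",
                 selected[bad[1]], selected[bad[2]]))
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(selected, selected)
  class(z) <- c("inter_fc", class(z))
  z
}

#' Reliably positive intra-network FC mask
#'
#' Voxel-wise one-sample t-test of the subjects' z-scored intra-network maps
#' against zero; voxels with positive t surviving Bonferroni family-wise
#' error correction over the in-mask voxels form the mask used for the
#' between-group comparison of that network.
#'
#' @param maps subject x voxel matrix of intra-network FC values.
#' @param alpha FWE level.
#' @return logical vector over voxels; attribute `t` holds the t map.
#' @export
intra_fc_group_mask <- function(maps, alpha = 0.05) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2) stop("need at least 2 subjects")
  m <- colMeans(maps)
  s <- sqrt(colSums(sweep(maps, 2, m)^2) / (n - 1))
  t_ <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  p <- 2 * stats::pt(-abs(t_), n - 1)
  keep <- t_ > 0 & p < alpha / length(t_)
  if (!any(keep))
    warning("no voxel survives the positive-FC mask; downstream comparison skipped")
  structure(keep, t = t_)
}
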