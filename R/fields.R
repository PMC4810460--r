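# 3-D scalar-field utilities shared by the synthetic generator and the
# Monte-Carlo cluster correction: separable Gaussian smoothing and
# connected-component labeling under a metric neighborhood.

#' Separable Gaussian smoothing of a 3-D array
#'
#' Smooths with a Gaussian kernel specified by its full width at half
#' maximum in millimetres, given the voxel size. The 1-D kernel is truncated
#' at 3 sigma and renormalized row-wise at the array edges.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm full width at half maximum, mm; 0 returns `x` unchanged.
#' @param voxel_mm isotropic voxel edge length, mm.
#' @return smoothed array, same dimensions.
#' @export
gaussian_smooth3d <- function(x, fwhm_mm, voxel_mm = 3) {
  stopifnot(length(dim(x)) == 3)
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm   # in voxels
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  d <- dim(x)
  smooth_mat <- function(n) {
    # banded convolution matrix with edge renormalization
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      w <- k[j - i + half + 1L]
      m[i, j] <- w / sum(w)
    }
    m
  }
  # axis 1
  x <- array(smooth_mat(d[1]) %*% matrix(x, d[1]), d)
  # axis 2
  x <- aperm(array(smooth_mat(d[2]) %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  x <- aperm(array(smooth_mat(d[3]) %*% matrix(aperm(x, c(3, 1, 2)), d[3]),
                   d[c(3, 1, 2)]), c(2, 3, 1))
  x
}

#' Neighbor offsets implied by a connection radius
#'
#' All voxel offsets in the 3x3x3 neighborhood whose physical centre-to-centre
#' distance does not exceed `radius_mm`. With 3 mm voxels and the 5 mm radius
#' this yields face and edge neighbors (18-connectivity) and excludes
#' corners (5.196 mm).
#'
#' @param radius_mm connection radius, mm.
#' @param voxel_mm voxel edge length, mm.
#' @return integer matrix, one offset (dx, dy, dz) per row.
#' @export
neighbor_offsets <- function(radius_mm = 5, voxel_mm = 3) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- sqrt(rowSums((g * voxel_mm)^2))
  off <- g[d > 0 & d <= radius_mm + 1e-9, , drop = FALSE]
  if (nrow(off) == 0) stop("connection radius smaller than one voxel")
  off
}

#' Label connected clusters of suprathreshold voxels
#'
#' Flood-fill connected-component labeling of a logical 3-D array under the
#' neighbor set implied by a connection radius.
#'
#' @param supra logical 3-D array (TRUE = suprathreshold).
#' @param offsets neighbor offsets from [neighbor_offsets()].
#' @return list: `labels` (integer array, 0 = background), `sizes` (integer
#'   vector of cluster extents, decreasing).
#' @export
label_clusters <- function(supra, offsets = neighbor_offsets()) {
  d <- dim(supra)
  stopifnot(length(d) == 3)
  labels <- array(0L, d)
  idx <- which(supra)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  coords <- arrayInd(idx, d)
  rownames(coords) <- NULL
  lin <- function(co) co[, 1] + d[1] * (co[, 2] - 1L) + d[1] * d[2] * (co[, 3] - 1L)
  current <- 0L
  sizes <- integer(0)
  for (start in idx) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      co <- arrayInd(v, d)
      nb <- sweep(offsets, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (any(ok)) {
        nl <- lin(nb[ok, , drop = FALSE])
        nl <- nl[supra[nl] & labels[nl] == 0L]
        if (length(nl)) {
          labels[nl] <- current
          queue <- c(queue, nl)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  list(labels = labels, sizes = sizes[ord])
}
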