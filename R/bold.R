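#' A masked BOLD run
#'
#' One subject's 4-D acquisition flattened to a time x voxel matrix over the
#' in-mask voxels, keeping the 3-D grid and TR as metadata. Column `j` of
#' `data` is the timecourse of the voxel at `which(mask)[j]`.
#'
#' @param data numeric time x voxel matrix.
#' @param mask logical 3-D array; `sum(mask)` must equal `ncol(data)`.
#' @param TR repetition time, seconds.
#' @param subject subject identifier.
#' @param group optional group label.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, mask, TR, subject = NA_character_, group = NA_character_) {
  data <- as.matrix(data)
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a 3-D array")
  mask <- mask != 0
  if (sum(mask) != ncol(data))
    stop(sprintf("mask has %d voxels but data has %d columns", sum(mask), ncol(data)))
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains missing or non-finite values")
  stopifnot_scalar(TR, "TR", positive = TRUE)
  structure(list(data = data, mask = mask, TR = TR,
                 subject = subject, group = group),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("BOLD run '%s'%s: %d volumes x %d voxels (grid %s, TR %.3g s)\n",
              x$subject,
              if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
              nrow(x$data), ncol(x$data),
              paste(dim(x$mask), collapse = "x"), x$TR))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

# restrict a run to a subset of volumes (used for condition-specific FC)
subset_volumes <- function(run, idx) {
  stopifnot(inherits(run, "bold_run"))
  if (length(idx) == 0) stop("no volumes to retain")
  if (any(idx < 1 | idx > nrow(run$data))) stop("volume index out of range")
  out <- run
  out$data <- run$data[idx, , drop = FALSE]
  out
}
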