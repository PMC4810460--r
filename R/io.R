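# File formats: NIfTI volumes (via RNifti), TSV tables, YAML configs and
# JSON manifests.

#' Write a BOLD run (and optionally its mask) as NIfTI
#'
#' The 4-D data are unflattened onto the grid (out-of-mask voxels zero) and
#' written as NIfTI-1 with the TR in the time pixdim.
#'
#' @param run a [bold_run()].
#' @param path output `.nii`/`.nii.gz` path.
#' @param mask_path optional path for the 3-D mask volume.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path, mask_path = NULL) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$mask)
  vol <- array(0, c(d, nrow(run$data)))
  idx <- which(run$mask)
  for (t_ in seq_len(nrow(run$data)))
    vol[idx + (t_ - 1) * prod(d)] <- run$data[t_, ]
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, run$TR))
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path))
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(run$mask), d)), mask_path)
  invisible(path)
}

#' Read a BOLD run from NIfTI
#'
#' @param path 4-D NIfTI run.
#' @param mask_path 3-D NIfTI mask; non-binary values are binarized (> 0)
#'   with a warning.
#' @param subject,group metadata to attach.
#' @return a [bold_run()].
#' @export
read_bold_run <- function(path, mask_path, subject = NA_character_,
                          group = NA_character_) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop("expected a 4-D NIfTI run, got ", length(dim(img)), "-D: ", path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(msk)) != 3)
    stop("expected a 3-D NIfTI mask: ", mask_path)
  if (!all(dim(img)[1:3] == dim(msk)))
    stop("mask grid does not match the run grid")
  vals <- unique(as.vector(msk))
  if (!all(vals %in% c(0, 1)))
    warning("mask is not binary; binarizing at > 0")
  mask <- array(as.vector(msk) > 0, dim(msk))
  TR <- RNifti::pixdim(img)[4]
  if (!is.finite(TR) || TR <= 0) TR <- 1
  d <- dim(img)
  data <- t(matrix(as.vector(img), prod(d[1:3]), d[4])[which(mask), , drop = FALSE])
  bold_run(data, mask, TR, subject = subject, group = group)
}

#' Write component maps as a 4-D NIfTI (component as 4th axis)
#'
#' @param maps component x voxel matrix.
#' @param mask logical 3-D array defining the voxel order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maps_nifti <- function(maps, mask, path) {
  d <- dim(mask)
  vol <- array(0, c(d, nrow(maps)))
  idx <- which(mask)
  for (i in seq_len(nrow(maps)))
    vol[idx + (i - 1) * prod(d)] <- maps[i, ]
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Converts a YAML file with `cohort`, `ica`, `fc` and `alphasim` sections
#' into the argument lists [run_pipeline()] consumes; absent sections fall
#' back to package defaults.
#'
#' @param path YAML file.
#' @return named list of configuration sections.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
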