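#' Block task design
#'
#' Describes an alternating block design as an ordered sequence of blocks,
#' each with a condition label and a trial count. Trials have a fixed
#' duration; the instruction screen shown at the start of each block occupies
#' the block's first trial slot, so a block lasts `n_trials * trial_duration`
#' seconds. Volumes are acquired every `TR` seconds and the total block
#' duration must tile exactly into volumes.
#'
#' @param blocks data.frame with columns `condition` (character) and
#'   `n_trials` (positive integer); rows are presented in order.
#' @param trial_duration trial length in seconds.
#' @param instruction_duration instruction screen length in seconds (occupies
#'   the first trial slot; informational, not added to the block length).
#' @param TR repetition time in seconds.
#' @return An object of class `task_design`.
#' @seealso [nback_design()] for the 0-back/1-back preset.
#' @export
task_design <- function(blocks, trial_duration = 2, instruction_duration = 2,
                        TR = 2) {
  stopifnot_scalar(trial_duration, "trial_duration", positive = TRUE)
  stopifnot_scalar(instruction_duration, "instruction_duration", positive = TRUE)
  stopifnot_scalar(TR, "TR", positive = TRUE)
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) > 0) {
    if (!all(c("condition", "n_trials") %in% names(blocks)))
      stop("`blocks` needs columns `condition` and `n_trials`")
    if (any(blocks$n_trials < 1) || any(blocks$n_trials != round(blocks$n_trials)))
      stop("`n_trials` must be positive integers")
    block_secs <- blocks$n_trials * trial_duration
    if (any(abs(block_secs / TR - round(block_secs / TR)) > 1e-9))
      stop("each block's duration must be an integer number of TRs")
  }
  structure(list(blocks = blocks, trial_duration = trial_duration,
                 instruction_duration = instruction_duration, TR = TR),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Block task design: %d blocks, trial %.3gs, TR %.3gs, %d volumes\n",
              nrow(x$blocks), x$trial_duration, x$TR, n_volumes(x)))
  if (nrow(x$blocks)) {
    tab <- table(x$blocks$condition)
    for (cond in names(tab))
      cat(sprintf("  %s: %d blocks, %d trials total\n", cond, tab[[cond]],
                  sum(x$blocks$n_trials[x$blocks$condition == cond])))
  }
  invisible(x)
}

#' The alternating 0-back/1-back working-memory design
#'
#' Six 0-back blocks of 11 trials alternate with five 1-back blocks of
#' 12 trials (each block's first trial slot is the 2 s instruction screen).
#' With 2 s trials and a 2 s TR this gives 6*22 + 5*24 = 252 s = 126 volumes.
#'
#' @param TR repetition time in seconds.
#' @return A `task_design`.
#' @examples
#' d <- nback_design()
#' n_volumes(d)   # 126
#' @export
nback_design <- function(TR = 2) {
  condition <- rep(c("0-back", "1-back"), length.out = 11L)
  n_trials <- ifelse(condition == "0-back", 11L, 12L)
  task_design(data.frame(condition = condition, n_trials = n_trials),
              trial_duration = 2, instruction_duration = 2, TR = TR)
}

#' Number of volumes in a design
#' @param design a `task_design`.
#' @return integer volume count.
#' @export
n_volumes <- function(design) {
  stopifnot(inherits(design, "task_design"))
  if (nrow(design$blocks) == 0) return(0L)
  as.integer(round(sum(design$blocks$n_trials) * design$trial_duration / design$TR))
}

# volumes per block, in presentation order
block_volumes <- function(design) {
  if (nrow(design$blocks) == 0) return(integer(0))
  as.integer(round(design$blocks$n_trials * design$trial_duration / design$TR))
}

#' Condition boxcar at volume resolution
#'
#' @param design a `task_design`.
#' @param condition a condition label present in the design.
#' @return numeric 0/1 vector of length [n_volumes()].
#' @export
boxcar_regressor <- function(design, condition) {
  stopifnot(inherits(design, "task_design"))
  if (nrow(design$blocks) == 0) return(numeric(0))
  if (!condition %in% design$blocks$condition)
    stop(sprintf("condition '%s' not present in design", condition))
  nv <- block_volumes(design)
  rep(as.numeric(design$blocks$condition == condition), times = nv)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The widely used canonical HRF: a gamma density peaking around 5-6 s minus
#' a scaled gamma undershoot peaking around 15-16 s, sampled at the TR.
#'
#' @param TR sampling interval in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds, with
#'   unit dispersion these are approximately the peak/undershoot times).
#' @param ratio undershoot amplitude relative to the peak.
#' @param duration kernel support in seconds.
#' @param normalize `"sum"` scales the kernel to sum to 1, `"peak"` to
#'   maximum 1, `"none"` leaves the raw difference of densities.
#' @return An object of class `hrf_kernel`: list with `values` (sampled
#'   kernel), `times` and `params`.
#' @export
canonical_hrf <- function(TR, peak_delay = 6, undershoot_delay = 16,
                          ratio = 1/6, duration = 32,
                          normalize = c("sum", "peak", "none")) {
  stopifnot_scalar(TR, "TR", positive = TRUE)
  normalize <- match.arg(normalize)
  times <- seq(0, duration, by = TR)
  values <- hrf_shape(times, peak_delay, undershoot_delay, ratio)
  values <- switch(normalize,
                   sum  = values / sum(values),
                   peak = values / max(values),
                   none = values)
  structure(list(values = values, times = times,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               ratio = ratio, duration = duration,
                               normalize = normalize)),
            class = "hrf_kernel")
}

# raw double-gamma shape (unit dispersion on both gammas)
hrf_shape <- function(t, peak_delay = 6, undershoot_delay = 16, ratio = 1/6) {
  stats::dgamma(t, shape = peak_delay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
}

#' Convolve a boxcar with an HRF kernel
#'
#' Discrete causal convolution, truncated to the length of the input
#' regressor (the acquisition length).
#'
#' @param x numeric stimulus vector at volume resolution.
#' @param kernel an `hrf_kernel` (or bare numeric kernel).
#' @return numeric vector, same length as `x`.
#' @export
convolve_regressor <- function(x, kernel) {
  k <- if (inherits(kernel, "hrf_kernel")) kernel$values else as.numeric(kernel)
  if (length(x) == 0) return(numeric(0))
  full <- stats::convolve(x, rev(k), type = "open")
  full[seq_along(x)]
}

#' Volume indices for one condition, with hemodynamic delay
#'
#' Returns the (1-based, temporally ordered) indices of the volumes acquired
#' during a condition's blocks, each shifted forward by `delay_volumes` to
#' compensate the hemodynamic lag. Shifted indices past the end of the run
#' are dropped (truncated, never wrapped). Downstream consumers concatenate
#' the retained volumes contiguously.
#'
#' @param design a `task_design`.
#' @param condition condition label.
#' @param delay_volumes non-negative integer shift in volumes.
#' @return integer vector of retained volume indices.
#' @export
condition_volumes <- function(design, condition, delay_volumes = 0L) {
  stopifnot(inherits(design, "task_design"))
  if (delay_volumes < 0) stop("`delay_volumes` must be >= 0")
  if (nrow(design$blocks) == 0) return(integer(0))
  if (!condition %in% design$blocks$condition)
    stop(sprintf("condition '%s' not present in design", condition))
  nv <- block_volumes(design)
  total <- sum(nv)
  ends <- cumsum(nv)
  starts <- ends - nv + 1L
  sel <- which(design$blocks$condition == condition)
  idx <- unlist(lapply(sel, function(b) seq(starts[b], ends[b])), use.names = FALSE)
  idx <- idx + as.integer(delay_volumes)
  idx <- idx[idx <= total]
  if (length(idx) == 0)
    warning("delay leaves no retained volumes for condition '", condition, "'")
  sort(idx)
}

#' Task contrast regressor for a design
#'
#' HRF-convolved contrast between two conditions (by default 1-back minus
#' 0-back), the regressor used to estimate working-memory-load activation.
#'
#' @param design a `task_design`.
#' @param on condition coding +1.
#' @param off condition coding -1; `NULL` for a plain single-condition
#'   regressor.
#' @param kernel an `hrf_kernel`; default `canonical_hrf(design$TR)`.
#' @return numeric regressor of length [n_volumes()].
#' @export
task_regressor <- function(design, on = "1-back", off = "0-back",
                           kernel = NULL) {
  kernel <- kernel %||% canonical_hrf(design$TR)
  x <- boxcar_regressor(design, on)
  if (!is.null(off)) x <- x - boxcar_regressor(design, off)
  convolve_regressor(x, kernel)
}
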