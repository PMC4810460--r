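# Group spatial ICA: MDL order selection, two-step PCA reduction, Infomax
# unmixing with ICASSO stabilization, and dual-regression back-reconstruction.

#' Estimate the number of components by minimum description length
#'
#' Computes the eigenspectrum of the time x time covariance of each
#' temporally centered run (voxels as samples), averages the spectra across
#' runs, and minimizes the MDL criterion over candidate orders.
#'
#' @param runs list of [bold_run()] (or a single run).
#' @param max_order largest candidate order (default `T - 2`).
#' @return integer estimated order.
#' @export
mdl_order <- function(runs, max_order = NULL) {
  runs <- as_run_list(runs)
  T_ <- nrow(runs[[1]]$data)
  V <- ncol(runs[[1]]$data)
  ev <- Reduce(`+`, lapply(runs, function(r) {
    Xc <- sweep(r$data, 2, colMeans(r$data))
    eigen(tcrossprod(Xc) / V, symmetric = TRUE, only.values = TRUE)$values
  })) / length(runs)
  ev <- pmax(ev, max(ev) * 1e-12)
  if (max(ev) / min(ev) < 1 + 1e-9 && length(unique(round(ev, 12))) < 2)
    stop("degenerate covariance: rank < 2")
  p <- length(ev)
  kmax <- min(max_order %||% (p - 2L), p - 2L)
  # voxels are the i.i.d. samples of one covariance estimate; averaging run
  # spectra does not multiply the effective sample count
  N <- V
  mdl <- vapply(seq_len(kmax), function(k) {
    tail_ev <- ev[(k + 1):p]
    ratio <- exp(mean(log(tail_ev))) / mean(tail_ev)
    -N * (p - k) * log(ratio) + 0.5 * k * (2 * p - k + 1) * log(N)
  }, numeric(1))
  which.min(mdl)
}

as_run_list <- function(runs) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  if (!length(runs) || !all(vapply(runs, inherits, logical(1), "bold_run")))
    stop("`runs` must be one or more bold_run objects")
  V <- ncol(runs[[1]]$data)
  if (!all(vapply(runs, function(r) ncol(r$data) == V, logical(1))))
    stop("all runs must share the same voxel set")
  runs
}

#' Two-step PCA reduction for group ICA
#'
#' Step 1 reduces each subject's time dimension to `subject_order` principal
#' components; the reduced subject data are concatenated and step 2 reduces
#' the stack to `order` whitened components, retaining the operators.
#'
#' @param runs list of [bold_run()].
#' @param order final group order C.
#' @param subject_order per-subject retention (default `ceiling(1.5 * order)`,
#'   capped at the run length).
#' @return list of class `gica_pca`: `whitened` (C x voxel matrix with
#'   uncorrelated unit-variance rows), `dewhiten`, per-subject bases, and
#'   the retained variance fractions.
#' @export
two_step_pca <- function(runs, order, subject_order = NULL) {
  runs <- as_run_list(runs)
  T_ <- min(vapply(runs, function(r) nrow(r$data), integer(1)))
  subject_order <- subject_order %||% min(ceiling(1.5 * order), T_)
  if (order > subject_order)
    stop("`order` cannot exceed `subject_order`")
  if (subject_order > T_)
    stop("`subject_order` cannot exceed the number of time points")
  V <- ncol(runs[[1]]$data)
  step1 <- lapply(runs, function(r) {
    Xc <- sweep(r$data, 2, colMeans(r$data))
    e <- eigen(tcrossprod(Xc) / V, symmetric = TRUE)
    U1 <- e$vectors[, seq_len(subject_order), drop = FALSE]
    list(reduced = crossprod(U1, Xc), basis = U1,
         varexp = sum(e$values[seq_len(subject_order)]) / sum(pmax(e$values, 0)))
  })
  Z <- do.call(rbind, lapply(step1, `[[`, "reduced"))
  Zc <- Z - rowMeans(Z)
  e <- eigen(tcrossprod(Zc) / V, symmetric = TRUE)
  lam <- e$values[seq_len(order)]
  if (any(lam <= 0)) stop("group covariance rank below requested order")
  U2 <- e$vectors[, seq_len(order), drop = FALSE]
  whitening <- diag(1 / sqrt(lam), order) %*% t(U2)
  structure(list(whitened = whitening %*% Zc,
                 dewhiten = U2 %*% diag(sqrt(lam), order),
                 whitening = whitening,
                 subject_bases = lapply(step1, `[[`, "basis"),
                 subject_varexp = vapply(step1, `[[`, numeric(1), "varexp"),
                 group_varexp = sum(lam) / sum(pmax(e$values, 0)),
                 order = order, subject_order = subject_order),
            class = "gica_pca")
}

#' Infomax independent component analysis
#'
#' Batch natural-gradient Infomax with the logistic nonlinearity on whitened
#' data: spatial maps over voxels are the estimated sources. The learning
#' rate is annealed when an update overshoots; iteration stops at a weight-
#' change tolerance or `max_iter` (then a warning is raised and the result
#' flagged unconverged). Deterministic given `seed`.
#'
#' @param x whitened C x N matrix (components x voxels).
#' @param seed integer seed for the random orthogonal initialization.
#' @param lr initial learning rate.
#' @param max_iter,tol stopping rule.
#' @return list: `sources` (C x N, rows flipped to positive skewness),
#'   `unmixing` (C x C), `iterations`, `converged`.
#' @export
infomax_ica <- function(x, seed = 1L, lr = 0.05, max_iter = 1000L, tol = 1e-7) {
  C <- nrow(x); N <- ncol(x)
  if (C < 1 || N <= C) stop("whitened input must be components x samples")
  W <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(C * C), C))))
  I_C <- diag(C)
  dW_prev <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% x
    Y <- 1 / (1 + exp(-U))
    dW <- (I_C + (1 - 2 * Y) %*% t(U) / N) %*% W
    change <- sqrt(sum(dW^2) / sum(W^2)) * lr
    if (!is.finite(change) || change > 10) {   # blow-up: anneal and restart
      lr <- lr / 2
      W <- with_seed(seed + it, qr.Q(qr(matrix(stats::rnorm(C * C), C))))
      dW_prev <- NULL
      next
    }
    # anneal when the update direction reverses (overshoot past the optimum)
    if (!is.null(dW_prev) && sum(dW * dW_prev) < 0) lr <- lr * 0.8
    W <- W + lr * dW
    dW_prev <- dW
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("Infomax did not reach tolerance %.1e in %d iterations", tol, max_iter))
  S <- W %*% x
  flip <- sign_by_skewness(S)
  list(sources = S * flip, unmixing = W * flip, iterations = it,
       converged = converged)
}

# ICA sign is arbitrary; orient each map so its skewness is positive
# ("activation-positive" convention)
sign_by_skewness <- function(S) {
  sk <- apply(S, 1, function(v) {
    v <- v - mean(v); m2 <- mean(v^2)
    if (m2 == 0) 1 else mean(v^3) / m2^1.5
  })
  ifelse(sk >= 0, 1, -1)
}

#' ICASSO stabilization of Infomax ICA
#'
#' Re-runs Infomax with distinct seeds (optionally on bootstrap resamples of
#' the voxels), pools all estimated components, clusters them by average-
#' linkage agglomerative clustering on 1 - |correlation|, and returns one
#' centrotype per cluster (the member with maximal total within-cluster
#' similarity) plus a stability index per cluster: mean within-cluster
#' |correlation| minus mean between-cluster |correlation|.
#'
#' @param x whitened C x N matrix.
#' @param n_runs number of ICA restarts (>= 1; 1 returns that run's maps
#'   with stability 1 by convention).
#' @param seed integer; run seeds are derived from it.
#' @param bootstrap resample voxels for each run's estimation step.
#' @return An object of class `icasso_result`: `centrotypes` (C x N),
#'   `stability` (length C, in `[0, 1]` up to sampling noise), `unmixing`
#'   of the centrotype runs, `n_runs`, `cluster_sizes`.
#' @export
icasso <- function(x, n_runs = 100L, seed = 1L, bootstrap = FALSE) {
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  C <- nrow(x)
  seeds <- derive_seeds(seed, n_runs)
  fits <- lapply(seq_len(n_runs), function(i) {
    xi <- if (bootstrap)
      x[, with_seed(seeds[i] + 1L, sample.int(ncol(x), replace = TRUE)), drop = FALSE]
    else x
    fit <- suppressWarnings(infomax_ica(xi, seed = seeds[i]))
    fit$sources <- fit$unmixing %*% x   # evaluate sources on the full data
    fit
  })
  all_S <- do.call(rbind, lapply(fits, `[[`, "sources"))
  if (n_runs == 1L) {
    return(structure(list(centrotypes = fits[[1]]$sources,
                          stability = rep(1, C), n_runs = 1L,
                          cluster_sizes = rep(1L, C)),
                     class = "icasso_result"))
  }
  sim <- abs(stats::cor(t(all_S)))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = C)
  sizes <- as.integer(table(cl))
  if (any(sizes != n_runs))
    warning("estimate clusters are unbalanced; returning best-effort clusters")
  cents <- matrix(0, C, ncol(x))
  stability <- numeric(C)
  for (c_i in seq_len(C)) {
    members <- which(cl == c_i)
    within <- sim[members, members, drop = FALSE]
    cent <- members[which.max(rowSums(within))]
    cents[c_i, ] <- all_S[cent, ]
    w_mean <- if (length(members) > 1)
      mean(within[upper.tri(within)]) else 1
    b_mean <- mean(sim[members, -members, drop = FALSE])
    stability[c_i] <- w_mean - b_mean
  }
  flip <- sign_by_skewness(cents)
  structure(list(centrotypes = cents * flip, stability = stability,
                 n_runs = as.integer(n_runs), cluster_sizes = sizes),
            class = "icasso_result")
}

#' Dual-regression back-reconstruction
#'
#' Projects group spatial maps into one subject's data in two least-squares
#' steps, both with an intercept: (1) spatial regression of each time point
#' on the maps gives the subject's temporal components TC; (2) temporal
#' regression of each voxel's timecourse on TC gives the subject's spatial
#' components SC.
#'
#' @param run a [bold_run()] (or bare time x voxel matrix).
#' @param maps group spatial maps, component x voxel.
#' @return An object of class `subject_decomposition`: `tc` (time x
#'   component), `sc` (component x voxel), `zscored` flag.
#' @export
dual_regression <- function(run, maps) {
  X <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  maps <- as.matrix(maps)
  if (ncol(X) != ncol(maps))
    stop("voxel dimensions of the run and the maps disagree")
  q1 <- qr(cbind(1, t(maps)))
  if (q1$rank < nrow(maps) + 1) {
    dep <- setdiff(seq_len(nrow(maps) + 1), q1$pivot[seq_len(q1$rank)]) - 1L
    stop("group maps are rank deficient; dependent component(s): ",
         paste(dep, collapse = ", "))
  }
  tc <- t(qr.coef(q1, t(X))[-1, , drop = FALSE])
  q2 <- qr(cbind(1, tc))
  sc <- qr.coef(q2, X)[-1, , drop = FALSE]
  structure(list(tc = tc, sc = sc, zscored = FALSE,
                 subject = if (inherits(run, "bold_run")) run$subject else NA),
            class = "subject_decomposition")
}

#' Z-score a subject decomposition
#'
#' Standardizes each spatial-map row and each temporal-component column to
#' mean 0, SD 1 (the scaling applied before connectivity statistics).
#'
#' @param dec a `subject_decomposition`.
#' @return the decomposition with `zscored = TRUE`.
#' @export
zscore_decomposition <- function(dec) {
  stopifnot(inherits(dec, "subject_decomposition"))
  sd_sc <- apply(dec$sc, 1, stats::sd)
  sd_tc <- apply(dec$tc, 2, stats::sd)
  if (any(sd_sc == 0))
    stop("zero-variance spatial map for component(s): ",
         paste(which(sd_sc == 0), collapse = ", "))
  if (any(sd_tc == 0))
    stop("zero-variance timecourse for component(s): ",
         paste(which(sd_tc == 0), collapse = ", "))
  dec$sc <- (dec$sc - rowMeans(dec$sc)) / sd_sc
  dec$tc <- scale(dec$tc)[, , drop = FALSE]
  attr(dec$tc, "scaled:center") <- NULL
  attr(dec$tc, "scaled:scale") <- NULL
  dec$zscored <- TRUE
  dec
}

#' Fit a group spatial ICA model
#'
#' The front door of the decomposition stage: estimates the model order by
#' MDL (unless given), reduces the runs by two-step PCA, extracts stabilized
#' group spatial maps by Infomax + ICASSO, and returns a fitted object whose
#' `predict` method back-reconstructs any subject's decomposition by dual
#' regression.
#'
#' @param runs list of [bold_run()].
#' @param order group model order; `NULL` for automatic MDL selection.
#' @param n_icasso number of ICASSO restarts.
#' @param seed integer seed controlling every random draw of the fit.
#' @param subject_order step-1 per-subject PCA retention.
#' @return An object of class `gica` with components `maps` (component x
#'   voxel centrotypes), `order`, `stability`, `pca`, `mask`, `TR`.
#' @seealso [predict.gica()], [dual_regression()], [icasso()]
#' @examples
#' coh <- simulate_cohort(cohort_config(n_control = 3, n_patient = 3, seed = 2))
#' fit <- gica(coh$runs, order = 6, n_icasso = 5, seed = 2)
#' fit
#' dec <- predict(fit, coh$runs[[1]])
#' @export
gica <- function(runs, order = NULL, n_icasso = 10L, seed = 1L,
                 subject_order = NULL) {
  runs <- as_run_list(runs)
  order <- order %||% mdl_order(runs)
  pca <- two_step_pca(runs, order, subject_order)
  ic <- icasso(pca$whitened, n_runs = n_icasso, seed = seed)
  structure(list(maps = ic$centrotypes, order = order,
                 stability = ic$stability, icasso = ic, pca = pca,
                 mask = runs[[1]]$mask, TR = runs[[1]]$TR,
                 n_subjects = length(runs), seed = seed,
                 call = match.call()),
            class = "gica")
}

#' @export
print.gica <- function(x, ...) {
  cat(sprintf("Group spatial ICA: %d components from %d subjects (%d voxels)\n",
              x$order, x$n_subjects, ncol(x$maps)))
  cat(sprintf("ICASSO stability (%d runs): %s\n", x$icasso$n_runs,
              paste(sprintf("%.2f", x$stability), collapse = " ")))
  invisible(x)
}

#' @export
summary.gica <- function(object, ...) {
  out <- data.frame(component = seq_len(object$order),
                    stability = object$stability,
                    map_skewness = apply(object$maps, 1, function(v) {
                      v <- v - mean(v); mean(v^3) / mean(v^2)^1.5
                    }))
  attr(out, "group_varexp") <- object$pca$group_varexp
  class(out) <- c("summary.gica", class(out))
  out
}

#' @export
print.summary.gica <- function(x, ...) {
  cat(sprintf("Group ICA summary (retained group variance %.1f%%)\n",
              100 * attr(x, "group_varexp")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.gica <- function(object, ...) object$maps

#' Back-reconstruct a subject from a fitted group ICA
#'
#' Dual regression of a run on the fitted group maps, optionally z-scored.
#'
#' @param object a [gica()] fit.
#' @param newdata a [bold_run()] (or time x voxel matrix).
#' @param zscore standardize the resulting decomposition.
#' @param ... unused.
#' @return a `subject_decomposition`.
#' @export
predict.gica <- function(object, newdata, zscore = TRUE, ...) {
  dec <- dual_regression(newdata, object$maps)
  if (zscore) dec <- zscore_decomposition(dec)
  dec
}

#' Plot a fitted group component map
#'
#' Displays one axial slice of a component's spatial map on the analysis
#' grid (out-of-mask voxels are NA).
#'
#' @param x a [gica()] fit.
#' @param component component index.
#' @param slice axial slice index (default: slice with maximal energy).
#' @param ... passed to [graphics::image()].
#' @export
plot.gica <- function(x, component = 1L, slice = NULL, ...) {
  vol <- array(NA_real_, dim(x$mask))
  vol[x$mask] <- x$maps[component, ]
  if (is.null(slice)) {
    energy <- apply(vol, 3, function(s) sum(s^2, na.rm = TRUE))
    slice <- which.max(energy)
  }
  graphics::image(vol[, , slice], main = sprintf("component %d, slice %d",
                                                 component, slice),
                  xlab = "", ylab = "", ...)
  invisible(x)
}
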