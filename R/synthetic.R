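# Synthetic two-group block-design cohorts with known ground truth.
#
# Each subject's run is mixing_timecourses %*% spatial_maps + Gaussian noise.
# Designated task components carry an HRF-convolved 1-back regressor scaled
# by a per-group activation gain on top of an AR(1) background; a designated
# component pair has its background innovations correlated so the pair's
# total timecourses hit a per-group target correlation; patients additionally
# receive an intra-network coupling deficit (signal attenuated and replaced
# by noise of equal variance) in a planted voxel set of one component.

#' Configuration for a synthetic cohort
#'
#' Defaults define the reference study conditions: k = 6 networks on a
#' 12 x 12 x 10 grid with an ellipsoidal brain mask, 10 subjects per group,
#' the alternating 0-back/1-back design at TR = 2 s, AR(1) backgrounds
#' (phi = 0.3), per-blob-voxel SNR around 2, higher task activation gain in
#' patients, a between-network coupling drop of 0.4 Fisher-z units in
#' patients for the designated pair, and a planted intra-network coupling
#' deficit in patients for component 1. Components beyond the task set cover
#' the non-gray tissue classes and the cerebellum so that component
#' classification has every branch to exercise.
#'
#' @param n_control,n_patient subjects per group (>= 2).
#' @param grid 3-D grid dimensions.
#' @param k number of components (>= 2).
#' @param design a [task_design()]; its volume count is the run length.
#' @param noise_sd additive Gaussian noise SD (>= 0; 0 gives exact rank-k).
#' @param phi AR(1) coefficient of background timecourses.
#' @param activation_gain named per-group amplitude of the task-locked
#'   timecourse component (on a unit-variance regressor).
#' @param task_components indices of task-modulated (gray-matter) components.
#' @param inter_fc_pair length-2 component pair with controlled coupling.
#' @param inter_fc_corr named per-group target correlation between the
#'   pair's total timecourses.
#' @param intra_deficit list(component, n_voxels, scale): per-group coupling
#'   multiplier `scale` (patient < 1) applied at the component's strongest
#'   `n_voxels` voxels, with variance-preserving noise injection.
#' @param behavior list of per-group behavioral parameters: `accuracy`,
#'   `rt_mean` (ms), `rt_sd` (ms).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 10, n_patient = 10,
                          grid = c(12L, 12L, 10L), k = 6L,
                          design = nback_design(), noise_sd = 0.8,
                          phi = 0.3,
                          activation_gain = c(control = 0.8, patient = 1.04),
                          task_components = NULL,
                          inter_fc_pair = c(2L, 3L),
                          inter_fc_corr = c(control = 0.5,
                                            patient = tanh(atanh(0.5) - 0.4)),
                          intra_deficit = list(component = 1L, n_voxels = 30L,
                                               scale = c(control = 1, patient = 0.55)),
                          behavior = list(accuracy = c(control = 0.95, patient = 0.90),
                                          rt_mean = c(control = 600, patient = 650),
                                          rt_sd = c(control = 150, patient = 150)),
                          seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (k < 2) stop("`k` must be >= 2")
  if (n_control < 2 || n_patient < 2) stop("need at least 2 subjects per group")
  if (n_volumes(design) < 2 * k)
    stop("design too short: need at least 2*k volumes")
  if (any(behavior$accuracy <= 0) || any(behavior$accuracy > 1))
    stop("accuracy means must lie in (0, 1]")
  if (any(behavior$rt_sd < 0)) stop("RT SD must be >= 0")
  task_components <- task_components %||% seq_len(min(3L, k - 1L))
  structure(list(n_control = n_control, n_patient = n_patient,
                 grid = as.integer(grid), k = as.integer(k), design = design,
                 noise_sd = noise_sd, phi = phi,
                 activation_gain = activation_gain,
                 task_components = as.integer(task_components),
                 inter_fc_pair = as.integer(inter_fc_pair),
                 inter_fc_corr = inter_fc_corr,
                 intra_deficit = intra_deficit,
                 behavior = behavior, seed = as.integer(seed)),
            class = "cohort_config")
}

# ellipsoidal brain mask inscribed in the grid
ellipsoid_mask <- function(grid) {
  c0 <- (grid + 1) / 2
  r <- grid / 2
  co <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                              z = seq_len(grid[3])))
  d2 <- ((co[, 1] - c0[1]) / r[1])^2 + ((co[, 2] - c0[2]) / r[2])^2 +
    ((co[, 3] - c0[3]) / r[3])^2
  array(d2 <= 1, grid)
}

# Gaussian blob on the masked grid, thresholded to compact support
blob_map <- function(grid, mask, center, radius = 1.1) {
  co <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                              z = seq_len(grid[3])))
  d2 <- rowSums(sweep(co, 2, center)^2)
  v <- exp(-d2 / (2 * radius^2))
  v[v < 0.10] <- 0
  v[!as.vector(mask)] <- 0
  v[as.vector(mask)]
}

# well-separated blob centers (fractional grid coordinates, jittered);
# the last center sits low in z and posterior in y: the "cerebellum" slot
component_centers <- function(grid, k) {
  frac <- rbind(c(0.30, 0.30, 0.40), c(0.72, 0.30, 0.40),
                c(0.30, 0.72, 0.45), c(0.72, 0.72, 0.42),
                c(0.50, 0.38, 0.75), c(0.35, 0.62, 0.72),
                c(0.68, 0.58, 0.72), c(0.50, 0.72, 0.72))
  if (k > nrow(frac) + 1)
    stop("at most ", nrow(frac) + 1, " components supported by the center layout")
  centers <- frac[seq_len(k - 1), , drop = FALSE]
  cereb <- c(0.50, 0.80, 0.22)
  centers <- rbind(centers, cereb)[seq_len(k), , drop = FALSE]
  if (k < nrow(centers)) centers <- centers[seq_len(k), , drop = FALSE]
  sweep(centers, 2, grid - 1, `*`) + 1 + matrix(stats::runif(3 * k, -0.25, 0.25), k)
}

# AR(1) series with unit marginal variance from given innovations
ar1_series <- function(innov, phi) {
  as.numeric(stats::filter(innov * sqrt(1 - phi^2), phi,
                           method = "recursive"))
}

# background innovation correlation needed so the pair's *total* timecourses
# (gain * regressor + background) reach the target correlation
solve_background_corr <- function(rho_target, gain_i, gain_j) {
  c_needed <- rho_target * sqrt(gain_i^2 + 1) * sqrt(gain_j^2 + 1) -
    gain_i * gain_j
  if (abs(c_needed) > 0.99) {
    warning("target inter-network correlation unreachable; clipping")
    c_needed <- sign(c_needed) * 0.99
  }
  c_needed
}

#' Generate a synthetic two-group cohort
#'
#' Draws the shared spatial maps, per-subject mixing timecourses, BOLD runs,
#' behavioral records, covariates and a synthetic tissue atlas, all
#' deterministically from the config seed. See [cohort_config()] for the
#' generative model.
#'
#' @param config a [cohort_config()].
#' @return An object of class `wm_cohort`: list with `runs` (list of
#'   [bold_run()]), `behavior` (list of per-subject trial tables),
#'   `covariates` (data.frame), `atlas` (synthetic tissue atlas) and
#'   `truth` (ground-truth parameters, including the spatial maps, the
#'   per-subject mixing timecourses and the planted deficit voxels).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    grid <- config$grid; k <- config$k
    mask <- ellipsoid_mask(grid)
    V <- sum(mask)
    if (V < 10 * k)
      stop("grid too small: need at least 10*k in-mask voxels")
    centers <- component_centers(grid, k)
    maps <- t(vapply(seq_len(k), function(i) blob_map(grid, mask, centers[i, ]),
                     numeric(V)))
    # pairwise near-orthogonality of the blob maps
    nm <- maps / sqrt(rowSums(maps^2))
    cs <- abs(tcrossprod(nm)); diag(cs) <- 0
    if (max(cs) >= 0.2)
      warning(sprintf("spatial maps not near-orthogonal (max |cosine| = %.2f)",
                      max(cs)))

    roles <- component_roles(k, config$task_components)
    atlas <- synthetic_atlas(maps, mask, roles)

    design <- config$design
    T_ <- n_volumes(design)
    reg <- task_regressor(design, on = "1-back", off = NULL)
    reg <- (reg - mean(reg)) / stats::sd(reg)

    n_tot <- config$n_control + config$n_patient
    groups <- rep(c("control", "patient"),
                  c(config$n_control, config$n_patient))
    subjects <- sprintf("sub-%02d", seq_len(n_tot))

    pair <- config$inter_fc_pair
    deficit <- config$intra_deficit
    dc <- deficit$component
    deficit_voxels <- order(maps[dc, ], decreasing = TRUE)[seq_len(deficit$n_voxels)]

    runs <- vector("list", n_tot)
    tcs <- vector("list", n_tot)
    for (s in seq_len(n_tot)) {
      g <- groups[s]
      gain <- config$activation_gain[[g]]
      gains <- numeric(k)
      gains[config$task_components] <- gain
      innov <- matrix(stats::rnorm(T_ * k), T_, k)
      rho_b <- solve_background_corr(config$inter_fc_corr[[g]],
                                     gains[pair[1]], gains[pair[2]])
      innov[, pair[2]] <- rho_b * innov[, pair[1]] +
        sqrt(1 - rho_b^2) * innov[, pair[2]]
      bg <- apply(innov, 2, ar1_series, phi = config$phi)
      tc <- bg + outer(reg, gains)
      signal <- tc %*% maps
      # intra-network coupling deficit: attenuate component dc's contribution
      # at the planted voxels, restore variance with fresh noise
      sc <- deficit$scale[[g]]
      if (sc < 1) {
        mv <- maps[dc, deficit_voxels]
        sd_tc <- sqrt(gains[dc]^2 + 1)
        signal[, deficit_voxels] <- signal[, deficit_voxels] -
          (1 - sc) * tc[, dc] %*% t(mv) +
          matrix(stats::rnorm(T_ * length(deficit_voxels)), T_) *
            rep(abs(mv) * sd_tc * sqrt(1 - sc^2), each = T_)
      }
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(T_ * V, sd = config$noise_sd), T_, V)
      else 0
      runs[[s]] <- bold_run(signal + noise, mask, design$TR,
                            subject = subjects[s], group = g)
      tcs[[s]] <- tc
    }

    behavior <- simulate_behavior_records(design, groups, subjects,
                                          config$behavior)
    covariates <- simulate_covariates(groups, subjects)

    truth <- structure(list(spatial_maps = maps, mixing_timecourses = tcs,
                            mask = mask, roles = roles,
                            activation_gain = config$activation_gain,
                            task_regressor = reg,
                            inter_fc_pair = pair,
                            inter_fc_corr = config$inter_fc_corr,
                            intra_deficit = deficit,
                            deficit_voxels = deficit_voxels,
                            behavior_params = config$behavior,
                            seed = config$seed),
                       class = "wm_truth")
    structure(list(runs = runs, behavior = behavior, covariates = covariates,
                   atlas = atlas, truth = truth, config = config),
              class = "wm_cohort")
  })
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d control, %d patient), k = %d, %d voxels\n",
              length(x$runs), x$config$n_control, x$config$n_patient,
              x$config$k, sum(x$truth$mask)))
  invisible(x)
}

# tissue/cerebellum role per component: task components and any unassigned
# ones are gray matter; the last three slots (when k allows) cover white
# matter, a CSF-like class and the cerebellum
component_roles <- function(k, task_components) {
  tissue <- rep("gray", k)
  cereb <- logical(k)
  extra <- setdiff(seq_len(k), task_components)
  if (k >= 6 && length(extra) >= 3) {
    slots <- utils::tail(extra, 3)
    tissue[slots[1]] <- "white"
    tissue[slots[2]] <- "csf"
    cereb[slots[3]] <- TRUE       # cerebellar, gray tissue
  }
  list(tissue = tissue, cerebellum = cereb)
}

# synthetic tissue probability atlas consistent with the component roles
synthetic_atlas <- function(maps, mask, roles) {
  V <- ncol(maps)
  prob <- matrix(rep(c(0.70, 0.20, 0.10), each = V), V, 3,
                 dimnames = list(NULL, c("gray", "white", "csf")))
  for (i in seq_len(nrow(maps))) {
    vox <- maps[i, ] > 0
    if (roles$tissue[i] == "white")
      prob[vox, ] <- matrix(rep(c(0.15, 0.80, 0.05), each = sum(vox)), sum(vox))
    if (roles$tissue[i] == "csf")
      prob[vox, ] <- matrix(rep(c(0.15, 0.05, 0.80), each = sum(vox)), sum(vox))
  }
  cereb_idx <- which(roles$cerebellum)
  cerebellum <- if (length(cereb_idx)) maps[cereb_idx[1], ] > 0 else logical(V)
  structure(list(prob = prob, cerebellum = cerebellum, mask = mask),
            class = "tissue_atlas")
}

# per-trial behavioral draws (instruction trials carry no response)
simulate_behavior_records <- function(design, groups, subjects, params) {
  lapply(seq_along(groups), function(s) {
    g <- groups[s]
    rows <- do.call(rbind, lapply(seq_len(nrow(design$blocks)), function(b) {
      cond <- design$blocks$condition[b]
      n_resp <- min(10L, design$blocks$n_trials[b] - 1L)
      data.frame(subject = subjects[s], block = b, trial = seq_len(n_resp),
                 condition = cond,
                 correct = stats::runif(n_resp) < params$accuracy[[g]],
                 rt_ms = pmax(150, stats::rnorm(n_resp, params$rt_mean[[g]],
                                                params$rt_sd[[g]])))
    }))
    rows
  })
}

#' Generate behavioral records only
#'
#' The behavioral arm of the generator, usable without simulating imaging:
#' per-trial correct/incorrect Bernoulli draws and Gaussian RTs (truncated at
#' 150 ms) for each subject, under the configured per-group accuracy and RT
#' parameters.
#'
#' @param config a [cohort_config()] (only `design`, `behavior` and the group
#'   sizes are used).
#' @return list of per-subject trial data.frames (columns `subject`, `block`,
#'   `trial`, `condition`, `correct`, `rt_ms`).
#' @export
simulate_behavior <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(config$behavior$rt_sd < 0)) stop("RT SD must be >= 0")
  with_seed(config$seed, {
    groups <- rep(c("control", "patient"),
                  c(config$n_control, config$n_patient))
    subjects <- sprintf("sub-%02d", seq_along(groups))
    simulate_behavior_records(config$design, groups, subjects, config$behavior)
  })
}

# demographic and clinical covariates drawn from group-typical distributions
simulate_covariates <- function(groups, subjects) {
  draw <- function(g, mc, sc, mp, sp)
    ifelse(groups == "control", stats::rnorm(length(groups), mc, sc),
           stats::rnorm(length(groups), mp, sp))
  data.frame(subject = subjects, group = groups,
             age = round(draw(groups, 51.6, 6.2, 54.2, 8.8), 1),
             gender = ifelse(groups == "control",
                             stats::rbinom(length(groups), 1, 9 / 19),
                             stats::rbinom(length(groups), 1, 13 / 20)),
             education = round(draw(groups, 10.7, 2.3, 12.2, 2.7), 1),
             hba1c = pmax(4, draw(groups, 5.55, 0.32, 7.87, 2.12)),
             fbg = pmax(3.5, draw(groups, 4.84, 0.51, 6.96, 1.72)))
}

#' Simulate per-subject spatial FC maps with an optional planted deficit
#'
#' Generates subject-level intra-network connectivity maps directly at the
#' map level: each subject's map is a shared base pattern plus smoothed,
#' re-standardized Gaussian noise; patients can have a deficit of `d` noise
#' SDs subtracted at a planted voxel set. This is the input contract of
#' [voxelwise_group_compare()], used for calibration and planted-effect
#' studies where the full ICA path is not the object under test.
#'
#' @param n_control,n_patient group sizes.
#' @param mask logical 3-D array.
#' @param base numeric base map over in-mask voxels (default 0).
#' @param deficit_voxels integer indices (into in-mask voxels) of the planted
#'   region; `NULL` for a null cohort.
#' @param d deficit size in units of the between-subject map SD.
#' @param fwhm_mm,voxel_mm spatial smoothness of the subject noise.
#' @param seed integer seed.
#' @return list: `maps` (subject x voxel matrix), `group` (factor),
#'   `deficit_voxels`.
#' @export
simulate_fc_maps <- function(n_control, n_patient, mask, base = 0,
                             deficit_voxels = NULL, d = 0,
                             fwhm_mm = 6, voxel_mm = 3, seed = 1L) {
  with_seed(seed, {
    V <- sum(mask)
    grid <- dim(mask)
    n <- n_control + n_patient
    groups <- factor(rep(c("control", "patient"), c(n_control, n_patient)),
                     levels = c("control", "patient"))
    maps <- matrix(0, n, V)
    for (s in seq_len(n)) {
      field <- gaussian_smooth3d(array(stats::rnorm(prod(grid)), grid),
                                 fwhm_mm, voxel_mm)
      v <- field[mask]
      v <- (v - mean(v)) / stats::sd(v)
      maps[s, ] <- base + v
    }
    if (!is.null(deficit_voxels) && d != 0) {
      pat <- which(groups == "patient")
      maps[pat, deficit_voxels] <- maps[pat, deficit_voxels] - d
    }
    list(maps = maps, group = groups, deficit_voxels = deficit_voxels)
  })
}
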