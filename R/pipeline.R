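# End-to-end orchestration: design -> group ICA -> component selection ->
# condition-specific FC -> group inference -> behavioral report.

#' Run the full working-memory connectivity pipeline
#'
#' Chains every stage on a cohort (typically from [simulate_cohort()], or
#' assembled from files with [read_bold_run()]): group spatial ICA with
#' ICASSO, dual-regression back-reconstruction, tissue/task component
#' selection, condition-specific intra- and inter-network FC, positive-FC
#' masking, AlphaSim-corrected voxelwise group comparison per selected
#' network, uncorrected pairwise inter-network comparison, and the
#' behavioral/demographic group table. All artifacts can be written to
#' `out_dir` with a JSON manifest.
#'
#' @param cohort a `wm_cohort` (runs + behavior + covariates + atlas).
#' @param design a [task_design()].
#' @param order ICA order; `NULL` for MDL.
#' @param n_icasso ICASSO restarts.
#' @param fc_condition,fc_delay condition and hemodynamic delay (volumes)
#'   for the condition-specific decomposition.
#' @param spec an [alphasim_spec()] for the cluster correction.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param out_dir output directory; `NULL` skips writing.
#' @return list of class `wm_pipeline`: `fit` (the [gica()] object),
#'   `selection`, `intra_fc` (subject x voxel matrices per selected
#'   component), `masks`, `cluster_tables`, `inter_fc` (per-subject
#'   matrices), `inter_tests`, `behavior_table`, `manifest`.
#' @export
run_pipeline <- function(cohort, design = NULL, order = NULL, n_icasso = 10L,
                         fc_condition = "1-back", fc_delay = 3L,
                         spec = alphasim_spec(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "wm_cohort"))
  design <- design %||% cohort$config$design
  seeds <- derive_seeds(seed, 3)
  t0 <- Sys.time()
  log_stage <- function(stage, t_start)
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time() - t_start, units = "secs")))

  t1 <- Sys.time()
  fit <- gica(cohort$runs, order = order, n_icasso = n_icasso, seed = seeds[1])
  log_stage("group_ica", t1)

  t1 <- Sys.time()
  selection <- component_report(fit, cohort$runs, cohort$atlas, design)
  if (length(selection$selected) < 2)
    warning("fewer than 2 task-related components selected")
  log_stage("component_select", t1)

  t1 <- Sys.time()
  decs <- lapply(cohort$runs, condition_decomposition, maps = fit$maps,
                 design = design, condition = fc_condition,
                 delay_volumes = fc_delay)
  intra <- lapply(selection$selected, function(ci)
    do.call(rbind, lapply(decs, function(d) d$sc[ci, ])))
  names(intra) <- selection$selected
  inter <- if (length(selection$selected) >= 2)
    lapply(decs, inter_network_fc, selected = selection$selected) else NULL
  log_stage("network_fc", t1)

  t1 <- Sys.time()
  covs <- cohort$covariates
  spec_local <- spec
  spec_local$seed <- seeds[2]
  if (is.null(spec_local$df))               # match the adjusted t's df
    spec_local$df <- length(cohort$runs) - 5L
  masks <- list(); cluster_tables <- list()
  for (ci in as.character(selection$selected)) {
    mk <- suppressWarnings(intra_fc_group_mask(intra[[ci]]))
    masks[[ci]] <- mk
    if (!any(mk)) { cluster_tables[[ci]] <- NULL; next }
    vol_mask <- array(FALSE, dim(fit$mask))
    vol_mask[which(fit$mask)[mk]] <- TRUE
    ks <- alphasim_threshold(vol_mask, spec_local)
    cluster_tables[[ci]] <-
      voxelwise_group_compare(intra[[ci]][, mk, drop = FALSE], vol_mask, covs,
                              spec_local, k_star = ks$k)
  }
  inter_tests <- if (!is.null(inter) && length(cohort$runs) >= 4)
    inter_fc_group_compare(inter, covs) else NULL
  log_stage("inference", t1)

  t1 <- Sys.time()
  perf <- do.call(rbind, lapply(seq_along(cohort$behavior), function(s) {
    m <- behavior_metrics(cohort$behavior[[s]])
    data.frame(subject = covs$subject[s], group = covs$group[s],
               accuracy = m$accuracy, mean_rt = m$mean_rt, ies = m$ies)
  }))
  behav_vars <- c("accuracy", "mean_rt", "ies")
  behavior_table <- compare_groups(cbind(perf, covs[match(perf$subject, covs$subject),
                                                   c("age", "education", "hba1c", "fbg")]),
                                   group = "group",
                                   vars = c(behav_vars, "age", "education",
                                            "hba1c", "fbg"))
  log_stage("behavior", t1)

  out <- structure(list(fit = fit, selection = selection, intra_fc = intra,
                        masks = masks, cluster_tables = cluster_tables,
                        inter_fc = inter, inter_tests = inter_tests,
                        behavior_table = behavior_table, performance = perf,
                        seed = seed,
                        elapsed = as.numeric(Sys.time() - t0, units = "secs")),
                   class = "wm_pipeline")
  if (!is.null(out_dir)) out$manifest <- write_pipeline_outputs(out, cohort, out_dir)
  out
}

#' @export
print.wm_pipeline <- function(x, ...) {
  cat(sprintf("WM connectivity pipeline: %d components, %d selected, %.1fs\n",
              x$fit$order, length(x$selection$selected), x$elapsed))
  n_sig <- sum(vapply(x$cluster_tables, function(tb)
    if (is.null(tb)) 0L else sum(tb$significant), integer(1)))
  cat(sprintf("significant intra-network clusters: %d\n", n_sig))
  if (!is.null(x$inter_tests))
    cat(sprintf("inter-network pairs at p < 0.05 (uncorrected): %d of %d\n",
                sum(x$inter_tests$p < 0.05), nrow(x$inter_tests)))
  invisible(x)
}

# write maps, tables and a JSON manifest; returns the manifest
write_pipeline_outputs <- function(res, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$group_maps <- file.path(out_dir, "group_maps.nii.gz")
  write_maps_nifti(res$fit$maps, res$fit$mask, paths$group_maps)
  paths$component_report <- file.path(out_dir, "component_report.tsv")
  write_tsv(res$selection$report, paths$component_report)
  paths$behavior_table <- file.path(out_dir, "behavior_table.tsv")
  write_tsv(res$behavior_table, paths$behavior_table)
  paths$performance <- file.path(out_dir, "performance.tsv")
  write_tsv(res$performance, paths$performance)
  if (!is.null(res$inter_tests)) {
    paths$inter_tests <- file.path(out_dir, "inter_network_tests.tsv")
    write_tsv(res$inter_tests, paths$inter_tests)
  }
  for (ci in names(res$cluster_tables)) {
    if (is.null(res$cluster_tables[[ci]])) next
    p <- file.path(out_dir, sprintf("clusters_component_%s.tsv", ci))
    write_tsv(res$cluster_tables[[ci]], p)
    paths[[paste0("clusters_", ci)]] <- p
  }
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = res$seed,
                   n_subjects = length(cohort$runs),
                   order = res$fit$order,
                   selected = res$selection$selected,
                   outputs = paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
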