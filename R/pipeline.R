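#' @title End-to-end pipeline
#' @description Orchestrates the full analysis on a cohort: stereotypy
#'   rates and their group comparison; per-subject tractography and
#'   connectivity-based parcellation with data-driven selection of the
#'   number of subregions and a group MPM; BOLD denoising and seed FC per
#'   MPM subregion; voxel-wise group t maps with Monte-Carlo cluster
#'   correction; and the correlation between stereotypy rates and mean
#'   connectivity in the detected cluster (both groups pooled, with
#'   per-group correlations as secondary outputs).
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param total_recorded_min behavior normalization (minutes, default 120).
#' @param alpha normality-screen level for the behavior comparison.
#' @param k_range candidate subregion counts (default 2:5).
#' @param n_samples streamlines per seed voxel (default 200 at desk scale;
#'   see the methods vignette for the choice).
#' @param step_mm,max_steps,curvature_limit_deg,target_factor tracking
#'   parameters (see [seed_region_profiles()]).
#' @param denoise a [denoise_config()].
#' @param voxel_p,cluster_alpha,cluster_connectivity,n_iterations
#'   cluster-correction parameters (defaults: voxel p < .01, cluster alpha
#'   .05, 26-connectivity, 1000 Monte-Carlo iterations).
#' @param correlation_methods methods for the behavior-FC correlation;
#'   both Pearson and Spearman are reported by default.
#' @param rng_seed master seed for all pipeline randomness.
#' @return a `run_config` list.
#' @export
run_config <- function(total_recorded_min = 120, alpha = 0.05,
                       k_range = 2:5,
                       n_samples = 200L, step_mm = 0.5, max_steps = 200L,
                       curvature_limit_deg = 80, target_factor = 3L,
                       denoise = denoise_config(),
                       voxel_p = 0.01, cluster_alpha = 0.05,
                       cluster_connectivity = 26L, n_iterations = 1000L,
                       correlation_methods = c("pearson", "spearman"),
                       rng_seed = 1L) {
  if (voxel_p <= 0 || voxel_p >= 1 || cluster_alpha <= 0 || cluster_alpha >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(as.list(environment()), class = "run_config")
}

pipeline_behavior <- function(cohort, config) {
  rates <- stereotypy_rates(cohort$episodes,
                            total_recorded_min = config$total_recorded_min)
  test <- compare_groups(rates$rate_s_per_min, rates$group,
                         alpha = config$alpha)
  list(rates = rates, test = test)
}

pipeline_parcellate <- function(cohort, config) {
  seedmask <- cohort$phantom$seed
  profiles <- NULL
  sims <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    pr <- seed_region_profiles(
      s$field, seedmask, n_samples = config$n_samples,
      step_mm = config$step_mm, max_steps = config$max_steps,
      curvature_limit_deg = config$curvature_limit_deg,
      rng_seed = derive_seed(config$rng_seed, i, 10),
      target_factor = config$target_factor)
    sims[[i]] <- cross_correlation(pr)
    if (is.null(profiles)) profiles <- pr
  }
  k <- select_k(sims, k_range = config$k_range,
                rng_seed = derive_seed(config$rng_seed, 0, 11))
  labels <- attr(k, "labels")
  mpm <- group_mpm(labels, profiles$seed_voxels, cohort$phantom$grid,
                   k = as.integer(k))
  list(k = as.integer(k), k_table = attr(k, "table"),
       stable = attr(k, "stable"), labels = labels,
       seed_voxels = profiles$seed_voxels, mpm = mpm)
}

pipeline_rsfc <- function(cohort, config, mpm, threshold = NULL) {
  ph <- cohort$phantom
  k <- max(mpm$labels$labels)
  submasks <- lapply(seq_len(k), function(c1) label_volume(
    array(as.integer(mpm$labels$labels == c1), ph$grid$shape), ph$grid))
  groups <- vapply(cohort$subjects, `[[`, "", "group")
  fc <- lapply(seq_len(k), function(c1) vector("list",
                                               length(cohort$subjects)))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    dn <- denoise(s$bold, config$denoise, brain_mask = ph$brain,
                  wm_mask = ph$wm, csf_mask = ph$csf, motion = s$motion)
    for (c1 in seq_len(k))
      fc[[c1]][[i]] <- seed_fc_map(dn, submasks[[c1]], ph$brain,
                                   subject_id = s$subject_id)
  }
  if (is.null(threshold))
    threshold <- alphasim_threshold(
      ph$brain, voxel_p = config$voxel_p,
      cluster_alpha = config$cluster_alpha,
      smoothness_fwhm_mm = config$denoise$smooth_fwhm_mm,
      connectivity = config$cluster_connectivity,
      n_iterations = config$n_iterations,
      rng_seed = derive_seed(config$rng_seed, 0, 12),
      group_sizes = c(sum(groups == "MD"), sum(groups == "MR")))
  tmaps <- clusters <- vector("list", k)
  tabs <- list()
  for (c1 in seq_len(k)) {
    tmaps[[c1]] <- group_t_map(fc[[c1]][groups == "MD"],
                               fc[[c1]][groups == "MR"])
    clusters[[c1]] <- significant_clusters(tmaps[[c1]], threshold)
    tb <- clusters[[c1]]$table
    if (nrow(tb)) { tb$subregion <- c1; tabs[[length(tabs) + 1L]] <- tb }
  }
  cluster_table <- if (length(tabs)) do.call(rbind, tabs) else
    cbind(clusters[[1]]$table, subregion = integer(0))
  primary <- NULL
  cluster_means <- NULL
  if (nrow(cluster_table)) {
    best <- cluster_table[which.max(abs(cluster_table$peak_t)), ]
    c1 <- best$subregion
    idx <- which(as.vector(clusters[[c1]]$labels$labels) == best$cluster)
    primary <- list(subregion = c1, cluster = best$cluster,
                    peak_t = best$peak_t, sign = best$sign,
                    n_voxels = best$n_voxels, voxels = idx)
    cluster_means <- data.frame(
      subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
      group = groups,
      mean_fc_z = cluster_mean_fc(fc[[c1]], idx),
      stringsAsFactors = FALSE)
  }
  list(threshold = threshold, tmaps = tmaps, clusters = clusters,
       cluster_table = cluster_table, primary = primary,
       cluster_means = cluster_means, fc = fc, groups = groups)
}

pipeline_correlate <- function(rates, cluster_means, config) {
  if (is.null(cluster_means)) return(NULL)
  df <- merge(rates, cluster_means[, c("subject_id", "mean_fc_z")],
              by = "subject_id")
  out <- list()
  for (m in config$correlation_methods) {
    out[[paste0("pooled_", m)]] <-
      correlation_test(df$mean_fc_z, df$rate_s_per_min, method = m)
    for (gp in unique(df$group)) {
      sub <- df[df$group == gp, ]
      out[[paste0(tolower(gp), "_", m)]] <-
        correlation_test(sub$mean_fc_z, sub$rate_s_per_min, method = m)
    }
  }
  # group comparison of the cluster mean FC itself (MD vs MR)
  out$fc_group_test <- compare_groups(df$mean_fc_z, df$group)
  attr(out, "data") <- df
  out
}

#' Run the full analysis on an in-memory cohort
#'
#' Executes behavior scoring, tractography-based parcellation (with
#' select-k and group MPM), denoising, per-subregion seed FC, voxel-wise
#' group t maps with Monte-Carlo cluster correction, and the behavior-FC
#' correlation for the most significant surviving cluster. Deterministic
#' given `config$rng_seed`.
#'
#' @param cohort a `cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @param config a [run_config()].
#' @param threshold optional precomputed [alphasim_threshold()] result;
#'   when `NULL` it is computed from the cohort's brain mask and the
#'   config (identical inputs give identical thresholds, so a shared
#'   threshold may be reused across cohorts on the same mask).
#' @return object of class `amyg_report`.
#' @export
analyze_cohort <- function(cohort, config = run_config(), threshold = NULL) {
  beh <- pipeline_behavior(cohort, config)
  parc <- pipeline_parcellate(cohort, config)
  rs <- pipeline_rsfc(cohort, config, parc$mpm, threshold = threshold)
  corr <- pipeline_correlate(beh$rates, rs$cluster_means, config)
  structure(list(behavior = beh, parcellation = parc, rsfc = rs,
                 correlation = corr, config = config),
            class = "amyg_report")
}

#' @export
print.amyg_report <- function(x, ...) {
  cat("== amygdala-prefrontal pipeline report ==\n")
  cat(sprintf("behavior: MD vs MR rate comparison p = %.4g (%s)\n",
              x$behavior$test$p_two_tailed, x$behavior$test$method))
  cat(sprintf("parcellation: k = %d (stable: %s)\n", x$parcellation$k,
              x$parcellation$stable))
  nt <- nrow(x$rsfc$cluster_table)
  cat(sprintf("rsfc: %d significant cluster(s); extent threshold %d voxels\n",
              nt, x$rsfc$threshold$min_cluster_voxels))
  if (!is.null(x$rsfc$primary))
    cat(sprintf("  primary cluster: subregion %d, %d voxels, peak t = %.3f\n",
                x$rsfc$primary$subregion, x$rsfc$primary$n_voxels,
                x$rsfc$primary$peak_t))
  if (!is.null(x$correlation)) {
    pr <- x$correlation$pooled_pearson %||% x$correlation[[1]]
    cat(sprintf("correlation (pooled): r = %.4f, p = %.4g\n",
                pr$statistic, pr$p_two_tailed))
  }
  invisible(x)
}

report_json <- function(report) {
  tst <- function(t) if (is.null(t)) NULL else
    list(statistic = t$statistic, p_two_tailed = t$p_two_tailed,
         method = t$method, df = t$df, n1 = t$n1, n2 = t$n2,
         n_pairs = t$n_pairs)
  corr <- report$correlation
  list(
    behavior = list(test = tst(report$behavior$test),
                    rates = report$behavior$rates),
    parcellation = list(k = report$parcellation$k,
                        k_table = report$parcellation$k_table,
                        stable = report$parcellation$stable),
    rsfc = list(min_cluster_voxels = report$rsfc$threshold$min_cluster_voxels,
                cluster_table = report$rsfc$cluster_table,
                primary = if (!is.null(report$rsfc$primary))
                  report$rsfc$primary[c("subregion", "cluster", "peak_t",
                                        "sign", "n_voxels")]),
    correlation = if (!is.null(corr))
      lapply(corr[setdiff(names(corr), "fc_group_test")], tst),
    fc_group_test = if (!is.null(corr)) tst(corr$fc_group_test))
}

#' Run the pipeline on a cohort directory and write all outputs
#'
#' Reads a cohort written by [write_cohort()], runs [analyze_cohort()],
#' and writes rates, test results, the per-k selection table, the MPM and
#' per-subregion t maps and cluster label volumes (NIfTI), the cluster
#' table, per-subject cluster mean FC, the correlation results, and a
#' JSON report into `out_dir`.
#'
#' @param cohort_dir input cohort directory.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return the `amyg_report`, invisibly.
#' @export
run_full <- function(cohort_dir, out_dir, config = run_config()) {
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S"),
                                     " [amygparc] ", ...)
  log_stage("reading cohort from ", cohort_dir)
  cohort <- read_cohort(cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage("behavior + parcellation + rsfc + correlation")
  report <- analyze_cohort(cohort, config)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$behavior$rates, "rates.tsv")
  wt(as.data.frame(report$behavior$test), "behavior_test.tsv")
  wt(report$parcellation$k_table, "k_table.tsv")
  write_volume(report$parcellation$mpm$labels, file.path(out_dir,
                                                         "mpm.nii.gz"))
  for (c1 in seq_along(report$rsfc$tmaps)) {
    write_volume(report$rsfc$tmaps[[c1]]$t,
                 file.path(out_dir, sprintf("tmap_subregion%d.nii.gz", c1)))
    write_volume(report$rsfc$clusters[[c1]]$labels,
                 file.path(out_dir,
                           sprintf("clusters_subregion%d.nii.gz", c1)))
  }
  wt(report$rsfc$cluster_table, "cluster_table.tsv")
  if (!is.null(report$rsfc$cluster_means))
    wt(report$rsfc$cluster_means, "cluster_means.tsv")
  if (!is.null(report$correlation)) {
    cr <- report$correlation
    ctab <- do.call(rbind, lapply(
      setdiff(names(cr), "fc_group_test"),
      function(nm) cbind(contrast = nm, as.data.frame(cr[[nm]]))))
    wt(ctab, "correlations.tsv")
  }
  jsonlite::write_json(report_json(report), file.path(out_dir,
                                                      "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_stage("outputs written to ", out_dir)
  invisible(report)
}
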