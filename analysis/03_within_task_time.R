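#!/usr/bin/env Rscript
# Within-task time-resolved decoding: per-subject timecourses, TFCE
# sign-flip cluster correction at the group level, per-timepoint Bayes
# factors, and electrode searchlight topographies at the report latencies.

source(file.path("analysis", "00_config.R"))
ensure_results()

ds <- load_dataset()
subjects <- names(ds$epochs)
tasks <- vapply(ds$config$tasks, `[[`, "", "task_id")

for (tk in tasks) {
  maps <- lapply(subjects, function(s)
    decode_timecourse(ds$epochs[[s]][[tk]], lambda = LAMBDA, k = K_FOLDS,
                      seed = derive_seed(MASTER_SEED, "within", s, tk)))
  ci <- montecarlo_cluster_stat(maps, n_iter = N_ITER,
                                seed = derive_seed(MASTER_SEED, "mc", tk))
  bf <- bf_timecourse(maps)
  st <- stack_maps(maps)
  write.csv(data.frame(time = st$axes$time, accuracy = colMeans(st$values),
                       t = ci$t_map, p_corrected = ci$p,
                       significant = ci$mask, bf10 = bf$bf10,
                       band = bf$band),
            file.path(RESULTS_DIR, sprintf("within_time_%s.csv", tk)),
            row.names = FALSE)
  write.csv(ci$clusters,
            file.path(RESULTS_DIR, sprintf("within_clusters_%s.csv", tk)),
            row.names = FALSE)
  if (nrow(ci$clusters)) {
    main <- ci$clusters[which.max(ci$clusters$n_cells), ]
    message(sprintf("%s: largest significant cluster %g-%g ms (peak t = %.1f)",
                    tk, main$time_start, main$time_end, main$peak_stat))
  } else message(sprintf("%s: no significant cluster", tk))

  # searchlight topographies (first subject as example layer + group mean)
  sls <- lapply(subjects, function(s)
    searchlight_time(ds$epochs[[s]][[tk]], k = K_FOLDS,
                     seed = derive_seed(MASTER_SEED, "sl", s, tk)))
  group_sl <- Reduce(`+`, lapply(sls, `[[`, "values")) / length(sls)
  gmap <- decoding_map(group_sl, sls[[1]]$axes)
  topo <- report_timepoints(gmap)
  write.csv(data.frame(channel = rownames(topo), topo, check.names = FALSE),
            file.path(RESULTS_DIR, sprintf("searchlight_topo_%s.csv", tk)),
            row.names = FALSE)
}
message("wrote within_time_*.csv, within_clusters_*.csv, searchlight_topo_*.csv")
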