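#' Full-run configuration
#'
#' Bundles every stage's configuration for [run_pipeline]. The single
#' `seed` fans out to per-stage seeds through [derive_seed], so any stage
#' can be re-run in isolation with identical results.
#'
#' @param synth a [synth_config] describing the dataset to simulate.
#' @param preprocess optional [preprocess_config]; `NULL` (default) uses
#'   the generator output as-is (it is already epoched at the target rate).
#' @param frequency a [frequency_config].
#' @param lambda LDA shrinkage used everywhere.
#' @param k cross-validation folds.
#' @param time_step grid spacing (ms) for cross-task generalization
#'   matrices.
#' @param cross_tasks task ids entering the cross-task analyses; defaults
#'   to every task whose recipe plants a conflict signal (tasks without one
#'   are the within-task-only baseline, mirroring the exclusion of
#'   no-signal tasks from generalization analyses).
#' @param cross_label label decoded across tasks (`"condition"` or
#'   `"response_hand"`).
#' @param n_perm per-subject label permutations for the frequency-domain
#'   null.
#' @param n_draws group-level resampling draws.
#' @param tfce list of TFCE/permutation parameters
#'   (`E`, `H`, `dh`, `n_iter`, `tails`, `alpha`).
#' @param bayes list with prior scale `r`.
#' @param seed master seed, recorded in every output.
#' @param out_dir run directory.
#' @export
run_config <- function(synth = synth_config(),
                       preprocess = NULL,
                       frequency = frequency_config(),
                       lambda = 0.01, k = 10, time_step = 20,
                       cross_tasks = NULL, cross_label = "condition",
                       n_perm = 100, n_draws = 10000,
                       tfce = list(E = 0.5, H = 2, dh = 0.1, n_iter = 1000,
                                   tails = "one", alpha = 0.05),
                       bayes = list(r = sqrt(2) / 2),
                       seed = 1L, out_dir = tempfile("mvparun")) {
  if (is.null(cross_tasks))
    cross_tasks <- vapply(Filter(function(t)
      t$evoked_amplitude != 0 || t$theta_amplitude != 0, synth$tasks),
      `[[`, character(1), "task_id")
  structure(list(synth = synth, preprocess = preprocess,
                 frequency = frequency, lambda = lambda, k = k,
                 time_step = time_step, cross_tasks = cross_tasks,
                 cross_label = cross_label, n_perm = n_perm,
                 n_draws = n_draws, tfce = tfce, bayes = bayes,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  stripped <- config[setdiff(names(config), "out_dir")]
  js <- jsonlite::toJSON(stripped, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  tmp <- tempfile()
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

# provenance-stamped CSV: every numeric output names config hash, seed,
# lambda and package version in comment lines
write_csv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d lambda=%g version=%s",
                     prov$hash, prov$seed, prov$lambda, prov$version), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a provenance-stamped CSV written by the pipeline
#' @param path file path.
#' @export
read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate, (optional) preprocess, behavior,
#' within-task time-domain decoding with TFCE cluster inference and Bayes
#' factors, frequency-domain decoding with the resampled permutation null,
#' and cross-task temporal generalization with cluster inference. All
#' tabular results are written under `config$out_dir` with provenance
#' stamps, plus a `manifest.json` naming the config hash, seed and the md5
#' of every artifact. Reruns with an identical config and seed are
#' byte-identical.
#'
#' @param config a [run_config].
#' @return (invisibly) a list with the run directory and in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(hash = config_hash(config), seed = config$seed,
               lambda = config$lambda,
               version = as.character(utils::packageVersion("conflictMVPA")))
  synth <- config$synth
  synth$seed <- derive_seed(config$seed, "simulate")
  ds <- stage("simulate", generate_dataset(synth))
  write_trial_table(ds$trial_table, file.path(config$out_dir, "trials.tsv"))

  if (!is.null(config$preprocess)) {
    ds$epochs <- stage("preprocess", lapply(ds$epochs, function(subj)
      lapply(subj, preprocess, config = config$preprocess)))
  }
  task_ids <- vapply(synth$tasks, `[[`, character(1), "task_id")
  subjects <- names(ds$epochs)

  beh <- stage("behavior", {
    summ <- summarize_behavior(ds$trial_table, screening_rules())
    eff <- conflict_effects(summ)
    tests <- do.call(rbind, lapply(task_ids, function(tk) {
      s <- summ$subject[summ$subject$task == tk, ]
      wide_acc <- split(s$accuracy, s$condition)
      wide_rt <- split(s$rt_ms, s$condition)
      rbind(cbind(task = tk, measure = "accuracy",
                  effect_summary(wide_acc$conflict, wide_acc$nonconflict,
                                 r = config$bayes$r)),
            cbind(task = tk, measure = "rt_ms",
                  effect_summary(wide_rt$conflict, wide_rt$nonconflict,
                                 r = config$bayes$r)))
    }))
    cors <- cross_task_correlations(eff, "d_rt_ms")
    list(summaries = summ, effects = eff, tests = tests, correlations = cors)
  })
  write_csv_prov(beh$summaries$group,
                 file.path(config$out_dir, "behavior_group.csv"), prov)
  write_csv_prov(beh$tests, file.path(config$out_dir, "behavior_tests.csv"),
                 prov)

  tf <- config$tfce
  within <- stage("within_task_time", {
    lapply(stats::setNames(task_ids, task_ids), function(tk) {
      maps <- lapply(subjects, function(s)
        decode_timecourse(ds$epochs[[s]][[tk]], lambda = config$lambda,
                          k = config$k,
                          seed = derive_seed(config$seed, "within", s, tk)))
      ci <- montecarlo_cluster_stat(maps, E = tf$E, H = tf$H, dh = tf$dh,
                                    n_iter = tf$n_iter, tails = tf$tails,
                                    alpha = tf$alpha,
                                    seed = derive_seed(config$seed, "mc", tk))
      bfs <- bf_timecourse(maps, r = config$bayes$r)
      list(maps = maps, inference = ci, bf = bfs)
    })
  })
  for (tk in task_ids) {
    st <- stack_maps(within[[tk]]$maps)
    write_csv_prov(data.frame(time = st$axes$time,
                              accuracy = colMeans(st$values),
                              significant = within[[tk]]$inference$mask,
                              bf10 = within[[tk]]$bf$bf10,
                              band = within[[tk]]$bf$band),
                   file.path(config$out_dir,
                             sprintf("within_time_%s.csv", tk)), prov)
    write_csv_prov(within[[tk]]$inference$clusters,
                   file.path(config$out_dir,
                             sprintf("within_clusters_%s.csv", tk)), prov)
  }

  freq <- stage("within_task_frequency", {
    do.call(rbind, lapply(task_ids, function(tk) {
      accs <- vapply(subjects, function(s)
        as.numeric(decode_frequency(ds$epochs[[s]][[tk]], config$frequency,
                                    lambda = config$lambda, k = config$k,
                                    seed = derive_seed(config$seed, "freq", s, tk))),
        0.0)
      perms <- t(vapply(subjects, function(s)
        permuted_accuracies(ds$epochs[[s]][[tk]], config$frequency,
                            n_perm = config$n_perm, lambda = config$lambda,
                            k = config$k,
                            seed = derive_seed(config$seed, "freqperm", s, tk)),
        numeric(config$n_perm)))
      nul <- stelzer_null(mean(accs), perms, n_draws = config$n_draws,
                          seed = derive_seed(config$seed, "stelzer", tk))
      bf <- bf10_ttest(x = accs - 0.5, r = config$bayes$r)
      data.frame(task = tk, mean_accuracy = mean(accs),
                 percentile = nul$percentile,
                 significant = nul$significant, bf10 = bf,
                 null_mean = mean(nul$group_draws))
    }))
  })
  write_csv_prov(freq, file.path(config$out_dir, "frequency_decoding.csv"),
                 prov)

  pairs <- if (length(config$cross_tasks) >= 2)
    utils::combn(config$cross_tasks, 2, simplify = FALSE) else list()
  cross <- stage("cross_task", {
    out <- list()
    for (pr in pairs) {
      for (dir in list(pr, rev(pr))) {
        keyname <- paste0(dir[1], "->", dir[2])
        maps <- lapply(subjects, function(s)
          cross_task_matrix(ds$epochs[[s]][[dir[1]]],
                            ds$epochs[[s]][[dir[2]]],
                            lambda = config$lambda,
                            seed = derive_seed(config$seed, "cross", s, keyname),
                            label = config$cross_label,
                            time_step = config$time_step))
        ci <- montecarlo_cluster_stat(maps, E = tf$E, H = tf$H, dh = tf$dh,
                                      n_iter = tf$n_iter, tails = tf$tails,
                                      alpha = tf$alpha,
                                      seed = derive_seed(config$seed, "mcx", keyname))
        st <- stack_maps(maps)
        bf <- bf10_map(st$values - 0.5, config$bayes$r)
        out[[keyname]] <- list(maps = maps, inference = ci, bf10 = bf)
      }
    }
    out
  })
  xsummary <- do.call(rbind, lapply(names(cross), function(kn) {
    ci <- cross[[kn]]$inference
    data.frame(pair = kn, n_cells = length(ci$mask),
               n_significant = sum(ci$mask),
               frac_bf01_gt3 = mean(1 / cross[[kn]]$bf10 > 3),
               max_t = max(ci$t_map))
  }))
  if (!is.null(xsummary))
    write_csv_prov(xsummary, file.path(config$out_dir, "cross_task_summary.csv"),
                   prov)
  for (kn in names(cross)) {
    ci <- cross[[kn]]$inference
    st <- stack_maps(cross[[kn]]$maps)
    grid <- expand.grid(train_time = ci$axes$train_time,
                        test_time = ci$axes$test_time)
    write_csv_prov(cbind(grid, accuracy = colMeans(st$values),
                         significant = as.vector(ci$mask),
                         bf10 = cross[[kn]]$bf10),
                   file.path(config$out_dir,
                             sprintf("cross_%s.csv", gsub("->", "_to_", kn))),
                   prov)
  }

  manifest_files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package = "conflictMVPA", version = prov$version,
    config_hash = prov$hash, seed = config$seed, lambda = config$lambda,
    tasks = task_ids, cross_tasks = config$cross_tasks,
    files = lapply(stats::setNames(manifest_files, manifest_files),
                   function(f) unname(tools::md5sum(file.path(config$out_dir, f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = config$out_dir, behavior = beh, within = within,
                 frequency = freq, cross = cross, manifest = manifest))
}

#' Render figures and tables from a completed run
#'
#' Produces, per task, the accuracy timecourse with its chance line,
#' significant-cluster underline and Bayes-factor panel (evidence bands at
#' 3 and 1/3); the frequency-domain summary; cross-task generalization
#' matrices with significance contours; and a behavioral summary table.
#' Figures are written as PDFs into `<run_dir>/figures`.
#'
#' @param run_dir directory written by [run_pipeline].
#' @return (invisibly) paths of the figures created.
#' @export
make_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stopf("missing artifact: manifest.json")
  fig_dir <- file.path(run_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  paths <- character(0)
  within_files <- list.files(run_dir, "^within_time_.*\\.csv$", full.names = TRUE)
  for (f in within_files) {
    tk <- sub("^within_time_(.*)\\.csv$", "\\1", basename(f))
    d <- read_csv_prov(f)
    sig <- d[d$significant, , drop = FALSE]
    p1 <- ggplot2::ggplot(d, ggplot2::aes(x = time, y = accuracy)) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
      ggplot2::geom_line() +
      (if (nrow(sig)) ggplot2::geom_point(data = sig,
         ggplot2::aes(y = min(d$accuracy) - 0.01), shape = 15, size = 0.8)
       else NULL) +
      ggplot2::labs(x = "time (ms)", y = "decoding accuracy", title = tk)
    p2 <- ggplot2::ggplot(d, ggplot2::aes(x = time, y = pmax(bf10, 1e-6))) +
      ggplot2::geom_hline(yintercept = c(1 / 3, 3), linetype = "dotted") +
      ggplot2::geom_line() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time (ms)", y = "BF10")
    out <- file.path(fig_dir, sprintf("within_%s.pdf", tk))
    grDevices::pdf(out, width = 7, height = 5)
    print(p1); print(p2)
    grDevices::dev.off()
    paths <- c(paths, out)
  }
  cross_files <- list.files(run_dir, "^cross_.*_to_.*\\.csv$", full.names = TRUE)
  for (f in cross_files) {
    d <- read_csv_prov(f)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = test_time, y = train_time,
                                         fill = accuracy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "steelblue",
                                    mid = "lightblue", high = "orange") +
      (if (any(d$significant))
        ggplot2::geom_point(data = d[d$significant, ], size = 0.2)
       else NULL) +
      ggplot2::labs(title = sub("\\.csv$", "", basename(f)),
                    x = "test time (ms)", y = "train time (ms)")
    out <- file.path(fig_dir, sub("\\.csv$", ".pdf", basename(f)))
    grDevices::pdf(out, width = 6, height = 5)
    print(p)
    grDevices::dev.off()
    paths <- c(paths, out)
  }
  beh_f <- file.path(run_dir, "behavior_group.csv")
  if (file.exists(beh_f)) {
    d <- read_csv_prov(beh_f)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = task, y = mean_rt_ms,
                                         fill = condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "mean RT (ms)")
    out <- file.path(fig_dir, "behavior.pdf")
    grDevices::pdf(out, width = 6, height = 4)
    print(p)
    grDevices::dev.off()
    paths <- c(paths, out)
  }
  invisible(paths)
}
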