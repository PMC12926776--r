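#!/usr/bin/env Rscript
# Behavioral pipeline: screening, per-condition summaries, paired
# conflict-vs-non-conflict tests with d_av and JZS Bayes factors, and
# cross-task Spearman correlations of the conflict effects.

source(file.path("analysis", "00_config.R"))
ensure_results()

ds <- load_dataset()
rules <- screening_rules(rt_max = c(taskA_change = 1800, taskB_simon = 1500,
                                    taskC_naming = 4000, taskD_reading = 4000,
                                    default = 4000))
summ <- summarize_behavior(ds$trial_table, rules)
write.csv(summ$group, file.path(RESULTS_DIR, "behavior_group.csv"),
          row.names = FALSE)

tests <- do.call(rbind, lapply(unique(summ$subject$task), function(tk) {
  s <- summ$subject[summ$subject$task == tk, ]
  acc <- split(s$accuracy, s$condition)
  rt <- split(s$rt_ms, s$condition)
  rbind(cbind(task = tk, measure = "accuracy",
              effect_summary(acc$conflict, acc$nonconflict)),
        cbind(task = tk, measure = "rt_ms",
              effect_summary(rt$conflict, rt$nonconflict)))
}))
write.csv(tests, file.path(RESULTS_DIR, "behavior_tests.csv"),
          row.names = FALSE)

eff <- conflict_effects(summ)
cors <- cross_task_correlations(eff, "d_rt_ms")
write.csv(cors$rho, file.path(RESULTS_DIR, "behavior_correlations_rho.csv"))
write.csv(cors$p, file.path(RESULTS_DIR, "behavior_correlations_p.csv"))

slower <- tests[tests$measure == "rt_ms", ]
message("conflict RT cost (conflict - nonconflict, ms) per task:")
for (i in seq_len(nrow(slower)))
  message(sprintf("  %s: %+.0f ms, t(%d) = %.1f, d_av = %.2f, BF10 = %.3g",
                  slower$task[i], slower$mean_diff[i], slower$df[i],
                  slower$t[i], slower$d_av[i], slower$bf10[i]))
message("wrote behavior_{group,tests,correlations_*}.csv")
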