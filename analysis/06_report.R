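#!/usr/bin/env Rscript
# Figures from the tables written by scripts 02-05: decoding timecourses
# with chance line, cluster underlines and Bayes-factor bands; frequency
# profiles; generalization matrices with significance dots; behavioral
# summaries.

source(file.path("analysis", "00_config.R"))
library(ggplot2)
fig_dir <- file.path(RESULTS_DIR, "figures")
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)

for (f in list.files(RESULTS_DIR, "^within_time_.*\\.csv$", full.names = TRUE)) {
  tk <- sub("^within_time_(.*)\\.csv$", "\\1", basename(f))
  d <- read.csv(f)
  sig <- d[d$significant, ]
  p1 <- ggplot(d, aes(time, accuracy)) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    geom_line(linewidth = 0.4) +
    {if (nrow(sig)) geom_point(data = sig, aes(y = min(d$accuracy) - 0.01),
                               shape = 15, size = 0.6)} +
    labs(x = "time (ms)", y = "decoding accuracy", title = tk)
  p2 <- ggplot(d, aes(time, pmax(bf10, 1e-8))) +
    geom_hline(yintercept = c(1 / 3, 3), linetype = "dotted") +
    geom_line(linewidth = 0.4) + scale_y_log10() +
    labs(x = "time (ms)", y = "BF10 (log scale)")
  pdf(file.path(fig_dir, sprintf("within_%s.pdf", tk)), width = 7, height = 5)
  print(p1); print(p2)
  dev.off()
}

fp <- file.path(RESULTS_DIR, "frequency_profiles.csv")
if (file.exists(fp)) {
  d <- read.csv(fp)
  p <- ggplot(d, aes(frequency, accuracy, color = task)) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    geom_line() +
    labs(x = "frequency (Hz)", y = "channel-averaged searchlight accuracy")
  pdf(file.path(fig_dir, "frequency_profiles.pdf"), width = 7, height = 4)
  print(p)
  dev.off()
}

for (f in list.files(RESULTS_DIR, "^cross_.*_to_.*\\.csv$", full.names = TRUE)) {
  d <- read.csv(f)
  p <- ggplot(d, aes(test_time, train_time, fill = accuracy)) +
    geom_raster() +
    scale_fill_gradient2(midpoint = 0.5, low = "steelblue",
                         mid = "lightblue", high = "orange") +
    {if (any(d$significant)) geom_point(data = d[d$significant, ], size = 0.1)} +
    labs(title = sub("\\.csv$", "", basename(f)),
         x = "test time (ms)", y = "train time (ms)")
  pdf(file.path(fig_dir, sub("\\.csv$", ".pdf", basename(f))),
      width = 6, height = 5)
  print(p)
  dev.off()
}

bg <- file.path(RESULTS_DIR, "behavior_group.csv")
if (file.exists(bg)) {
  d <- read.csv(bg)
  p <- ggplot(d, aes(task, mean_rt_ms, fill = condition)) +
    geom_col(position = "dodge") +
    geom_errorbar(aes(ymin = mean_rt_ms - sd_rt_ms,
                      ymax = mean_rt_ms + sd_rt_ms),
                  position = position_dodge(0.9), width = 0.2) +
    labs(y = "mean RT (ms)") +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
  pdf(file.path(fig_dir, "behavior.pdf"), width = 6, height = 4)
  print(p)
  dev.off()
}
message("figures written to ", fig_dir)
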