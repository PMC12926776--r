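# conflictMVPA

Multivariate EEG decoding of cognitive conflict, within and across tasks.

## The problem

Conflict tasks — Stroop, Simon, change detection with competing feature
changes — all slow people down and cost accuracy, but it is debated whether
the brain resolves them with **one domain-general mechanism**, **separate
task-specific modules**, or **partially overlapping machinery**. Scalp EEG
multivariate pattern analysis can adjudicate: if a linear classifier
trained to tell conflict from non-conflict trials in one task also works in
another task (*cross-task temporal generalization*), the two tasks share a
neural conflict code; if each task decodes only within itself, the codes
are task-specific. The package is for cognitive neurophysiologists who want
that full analysis stack — decoding, searchlights, generalization matrices,
calibrated group statistics — as tested, reusable R code, plus a synthetic
EEG generator in which the answer is planted and therefore recoverable.

## What is inside

* **Decoding core** — shrinkage-regularized LDA,
  `S' = (1−λ)S + λ(tr S/p)I`, `w = S'⁻¹(μ₁−μ₀)`, decision threshold at the
  midpoint of the projected class means (λ = 0.01 default; Woodbury
  data-space solve when features outnumber trials), with class-balanced
  stratified k-fold partitioning so chance is exactly 0.5.
* **Within-task analyses** — per-timepoint decoding over channels;
  electrode × timepoint and electrode × frequency single-feature
  searchlights; spectral decoding on 1–50 Hz DFT power of the 0–1000 ms
  window with fold-wise z-transformation.
* **Cross-task temporal generalization** — train on all balanced trials of
  one task at each timepoint, test at every timepoint of the other;
  directions kept separate; a response-hand decoding label provides the
  motor-transfer control analysis.
* **Group inference** — threshold-free cluster enhancement
  (`Σ_h extent^0.5 · h² · dh`) over chain, lattice or montage-graph
  neighborhoods with max-statistic sign-flip correction; a resampled
  label-permutation null for scalar accuracies (one permuted accuracy per
  subject per draw, percentile verdict at the 95th); JZS Bayes factors
  (Cauchy prior, scale √2/2) with evidence bands at 1/3, 3, 20, 150.
* **Behavior** — screening, condition summaries, paired tests with the
  paired-design effect size `d_av = |M₁−M₂| / ((SD₁+SD₂)/2)`, cross-task
  Spearman correlations of conflict effects.
* **Synthetic generator** — multi-subject, multi-task EEG with 1/f
  spatially mixed noise, an evoked conflict bump and induced theta on a
  fronto-central pattern, a per-task `overlap_alpha` dial setting how much
  of that pattern is shared across tasks, lognormal RTs and Bernoulli
  accuracy. Bit-reproducible under a seed.

## Worked example

The `analysis/` scripts run the whole workflow on a 12-subject synthetic
battery in which a change-detection-like task and a Stroop-naming-like task
share one conflict pattern, a Simon-like task carries an orthogonal one,
and a reading baseline has no conflict signal (`Rscript analysis/01_simulate.R`
through `06_report.R`; tables land in `results/`). The run prints, among
other things:

```
taskA_change: largest significant cluster 324-496 ms (peak t = 17.4)
taskB_simon: largest significant cluster 292-524 ms (peak t = 28.2)
taskC_naming: largest significant cluster 340-484 ms (peak t = 12.4)
taskD_reading: no significant cluster

taskA_change: accuracy 0.615 at percentile 100.0 (null mean 0.497), BF10 = 672
taskD_reading: accuracy 0.515 at percentile 87.2 (null mean 0.494), BF10 = 0.457
taskA_change: searchlight profile peaks at 6 Hz

taskA_change->taskC_naming (conflict): 39 significant cells, ...
taskB_simon->taskC_naming (conflict): 0 significant cells, ...
taskA_change->taskB_simon (response hand): 256 significant cells
```

Reading it: every task with a planted signal decodes within-task (clusters
bracketing the 400 ms effect latency; the no-signal baseline stays at
chance and its scalar accuracy sits below the 95th percentile of the
permutation null, BF10 < 1). The frequency searchlight peaks inside the
planted 3–7 Hz theta band. Crucially, cross-task decoding is significant
*only* between the two tasks that share a pattern — in both directions —
while the orthogonal task transfers nowhere despite decoding within-task,
and response-hand signals transfer across *every* pair, ruling out
methodological failure as the explanation for missing conflict transfer.
That significance pattern is the partially-overlapping-architecture
signature the package exists to detect.

A minimal programmatic session:

```r
library(conflictMVPA)
ds <- generate_dataset(synth_config(n_subjects = 20, seed = 1))
es <- ds$epochs$s01$change_detection
tc <- decode_timecourse(es, lambda = 0.01, k = 10, seed = 1)
maps <- lapply(ds$epochs, function(subj)
  decode_timecourse(subj$change_detection, seed = 1))
montecarlo_cluster_stat(maps, n_iter = 1000)   # TFCE cluster table
bf10_ttest(t = -2.43, n = 507)                 # 0.924
```

## Layout

```
R/                  package code (generator, preprocessing, decoder,
                    searchlights, generalization, inference, behavior,
                    pipeline orchestration)
src/                C++ kernels (LDA decoding loops, TFCE, sign-flip null)
analysis/           numbered workflow scripts over the package
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, parameters, design choices)
```
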