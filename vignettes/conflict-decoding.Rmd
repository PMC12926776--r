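---
title: "Decoding conflict processing within and across tasks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding conflict processing within and across tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

When the brain resolves cognitive conflict — a Stroop word fighting its ink
color, a Simon stimulus appearing on the wrong side, a distracting change in
a perceptual display — is the underlying neural machinery one
*domain-general* system, a set of *task-specific modules*, or something in
between? `conflictMVPA` operationalizes this question the way modern EEG
multivariate work does:

1. **Within-task decoding.** Train a regularized linear discriminant (LDA)
   to separate conflict from non-conflict trials inside each task, either
   per timepoint (all channels as features) or on spectral power features.
   Above-chance accuracy means the task carries a decodable conflict
   signature.
2. **Cross-task temporal generalization.** Train at each timepoint of one
   task, test at every timepoint of another. Transfer implies a *shared*
   neural code; its absence, given intact within-task decoding, implies
   task-specific codes. The pattern of which pairs transfer distinguishes
   the three architectures.
3. **Group inference.** Classification accuracies are not Gaussian nor
   centered at chance under the null in finite samples, so the package uses
   permutation-based machinery throughout: threshold-free cluster
   enhancement (TFCE) with max-statistic sign-flip correction for maps, a
   resampled label-permutation null for scalar accuracies, and JZS Bayes
   factors to quantify evidence for *and against* transfer.

The real dataset this design targets is access-restricted, so the package
ships a synthetic generator in which the architecture question has a known
answer, making the full pipeline testable end to end.

# The synthetic generator

Each trial of subject *s* in task *k* is

$$X(c, t) = \sigma \, N(c, t) \;+\; \mathbb{1}[\text{conflict}]\left(
  a_e\, b(t)\, p_k(c) \;+\; a_\theta\, g(t) \sin(2\pi f t + \phi)\, p_k(c)
  \right) \;+\; a_m\, h(t)\, s\, m(c),$$

with channels $c$, time $t$, and:

* **Background noise** $N$: per-channel $1/f^{\alpha}$ noise (default
  $\alpha = 1$, amplitude spectrum $f^{-\alpha/2}$ with uniform random
  phases), mixed across channels by a fixed row-normalized matrix
  $(1-s_m) I + s_m Q$ with $Q$ random orthogonal and $s_m$ the
  `spatial_mixing` strength (default 0.3). Row normalization keeps the
  per-channel SD equal to `noise_sd` (default 1 µV) regardless of mixing.
* **Evoked conflict effect**: a Gaussian bump $b(t)$ (default 400 ms
  latency, 80 ms SD, amplitude 1.2 µV), or a boxcar strictly confined to
  `evoked_window` when sharp-edged ground truth is needed (the cluster
  localization tests use this). It is added to conflict trials only.
* **Induced theta**: a sinusoid with per-trial random frequency inside
  `theta_band` (default 3–7 Hz) and per-trial random phase, gated to
  0–1000 ms. Random phase makes it invisible to trial-averaged ERPs and to
  per-timepoint *linear* decoding, but visible to spectral power features —
  this is precisely why the pipeline runs both a time-domain and a
  frequency-domain analysis, and the tests verify both sides of that
  dissociation.
* **Spatial patterns**: the conflict effect of task *k* loads on
  $p_k = \alpha_k \, p_{\text{shared}} + \sqrt{1-\alpha_k^2}\, u_k$, where
  $p_{\text{shared}}$ is a unit-norm fronto-central template (Gaussian in
  layout distance around a point between Fz and Cz — where conflict-related
  N2 and midfrontal theta are classically maximal) and $u_k$ is a
  task-specific unit vector orthogonal to it. `overlap_alpha` $\in [0,1]$
  is the single dial that moves a battery from fully domain-general
  ($\alpha = 1$ everywhere) to fully modular ($\alpha = 0$). Patterns are
  fixed across subjects, which is what makes *group-level* recovery
  possible.
* **Response-hand pattern**: an optional lateralized motor template $m(c)$
  ($x$-weighted central strip, sign $s = \pm 1$ by response hand, present
  in both conditions). It gives the response-hand *control* analysis its
  ground truth: hand decoding must transfer across all task pairs even
  when conflict patterns do not.
* **Behavior**: lognormal RTs and Bernoulli correctness per condition.
  Defaults make conflict trials slower and less accurate, with
  study-scale magnitudes; `lognormal_params(mean, sd)` maps intuitive
  moments onto `meanlog`/`sdlog`.

Draw order is documented and fixed (noise → theta frequency/phase →
response hand → RT → correctness), with all seeds derived from the master
seed by a tag-hash (`derive_seed`), so datasets are bit-reproducible and
any stage can be regenerated in isolation.

**What the generator does not emulate**: volume-conducted dipole forward
models, eye/muscle artifacts, trial-to-trial latency jitter of the evoked
response, autocorrelated behavior (post-conflict slowing), or inter-subject
topographic variability. Passing recovery tests therefore demonstrates the
*pipeline's* correctness and calibration, not that real EEG will show any
particular effect size; real-data effect sizes are typically an order of
magnitude smaller than the demo defaults, compensated in practice by the
much larger trial and subject counts.

The published trial counts are honored at their natural scale (e.g. ~76
conflict vs ~163 non-conflict trials for the change-detection-like task —
the class imbalance is deliberate and exercises the balanced partitioning).
Single-trial effect amplitudes are free parameters nowhere reported for the
real data; the defaults (about 1 µV effect against 1 µV noise) were chosen
once so that 10–20 synthetic subjects recover all planted structure, and
are not tuned per test.

# Preprocessing

The chain is deliberately minimal, reflecting the robustness of
multivariate decoding to residual noise: Hamming windowed sinc FIR
filtering, decimation to 250 Hz, task-specific epoching, baseline removal,
trial screening.

* **Filter cutoffs** (0.5–100 Hz) are package defaults — the filter family
  is fixed, cutoffs are configurable and recorded in provenance. The
  transition bandwidth is `min(max(cutoff/4, 2 Hz), cap)` where the cap
  (2·cutoff for high-pass, Nyquist − cutoff for low-pass) keeps the
  stopband edge inside the representable band; without the high-pass cap a
  0.5 Hz filter would leave DC inside its transition band and reject it
  only partially. Kernel length is the classic Hamming approximation
  `3.3 · fs / transition`, rounded up to odd, applied as a single forward
  pass with group-delay compensation (linear phase, so this is exactly
  zero-phase) and edge-replication padding.
* **Baseline window** is 0–200 ms *post-stimulus* by default. That is the
  convention of the published battery this design emulates; it is unusual
  (the common choice is pre-stimulus), so the window is fully configurable
  and every run records it in provenance rather than silently "fixing"
  it. All analyses
  here are condition contrasts at fixed time, for which any fixed baseline
  window is a per-trial affine shift and decoding conclusions are
  unaffected.
* **Screening** drops no-response trials, premature responses
  (RT < 100 ms by default — published batteries state this rule only
  qualitatively) and over-ceiling RTs (1800/1500/4000 ms task defaults).
  `correct_only` is off by default: the decoding methodology is not stated
  to use correct trials only, but both modes are supported.
* **Channel harmonization** reduces epoch sets to their common electrodes
  in alphabetical order; the shipped 28-channel montage stands in for the
  unspecified intersection of a 64- and a 32-channel cap.

# Decoding core

LDA with shrinkage toward the scaled identity:
$S' = (1-\lambda) S + \lambda \frac{\mathrm{tr}(S)}{p} I$,
$w = S'^{-1}(\mu_1 - \mu_0)$, threshold at the midpoint of projected class
means. $\lambda$ defaults to 0.01, the customary regularized-LDA default in
the MVPA toolboxes this field uses; because published analyses rarely
print their exact constant, every result in this package is reported
alongside its $\lambda$. In the $p > n$ regime (spectral features: 28 channels × 50 bins)
the same closed form is evaluated through the Woodbury identity in the
$n \times n$ data space. Decision-value ties go to the alphabetically first
class, for exact reproducibility.

Partitioning subsamples the majority class to the minority count (without
replacement, per balancing repeat) and stratifies both classes into k
folds of matching sizes, so every fold's train and test sets are exactly
balanced and chance is exactly 0.5. One partition per subject is reused
across all timepoints/cells of a map — re-drawing folds per cell would add
spurious cell-to-cell variance with no benefit.

Cross-task training uses *all* balanced trials of the training task (no
cross-validation: no training-task trial is ever scored) and subsamples
both tasks to a common per-condition count, removing both class and task
imbalance. The subsampling is per subject-pair, not per cell. Directions
A→B and B→A are computed and reported separately — asymmetric transfer is
scientifically meaningful and must not be averaged away.

Spectral features are bare-DFT power (no taper by default, Hann available)
on the half-open window [0, 1000) ms, which at 250 Hz gives exactly 250
samples and exact 1 Hz bins — the one place the package deviates from its
closed-interval window convention, because integer bin spacing is what
makes "the 3 Hz bin" well defined. Features are z-transformed fold-wise
(fitted on the training fold, reused on the test fold); a global
z-transform before cross-validation is available as an option for fidelity
comparisons with descriptions that permit that reading, and the difference
is negligible in practice while the fold-wise default is leakage-free by
construction. "Power alongside electrodes" is implemented as the standard
channel × frequency-bin feature set.

# Group inference

* **TFCE**: enhanced(p) = $\sum_h e(p,h)^{E} h^{H}\, dh$ with E = 0.5,
  H = 2, dh = 0.1, thresholds at exact multiples of dh up to the map
  maximum, over 1-D chains, 2-D lattices, or montage-graph neighborhoods.
  The implementation is union-find over an edge list (C++); the test suite
  holds it to an independent brute-force threshold-sum oracle at 1e-9.
* **Sign-flip max-statistic correction**: subject maps are centered at
  chance, the one-sample t-map is enhanced, and the null records the
  maximum enhanced value under random whole-map sign flips (10,000 by
  default; directional one-tailed by default since the hypotheses are
  "above chance"). The corrected p of a cell is the proportion of null
  maxima at least as large. Zero-variance cells take a sentinel
  t = ±100, and all |t| values are capped there: with few subjects the
  sample SD can approach zero and an uncapped t would make the fixed-dh
  threshold ladder astronomically long; the cap is far beyond any
  interpretable t value and cannot change which cells rank above a
  realistic null.
* **Resampled accuracy null**: per subject, the decoding is repeated with
  permuted labels (100 by default); each of 10,000 group draws averages one
  randomly chosen permuted accuracy per subject; the observed group mean is
  located as a midrank percentile (documented tie convention), significant
  above the 95th percentile. The tests verify the percentile is uniform
  under the null and that the draw distribution stays within one accuracy
  point of chance (mean ≥ 0.49) for balanced-CV accuracies. Classification
  nulls are known to be asymmetric around chance; in this package's
  leakage-free fold-wise z-scoring setup the measured deviation is a small
  *negative* finite-sample bias (≈ −1/n_trials), whereas published
  accounts reporting null distributions slightly *above* 0.5 are consistent
  with a global (pre-cross-validation) z-transformation, available here as
  the non-default `z_transform = "global"` option.
* **JZS Bayes factors**: the default Bayesian t-test (Cauchy prior on the
  standardized effect, scale $r = \sqrt{2}/2$), evaluated by adaptive
  quadrature on a log-scaled ratio form that stays finite up to
  BF ~ 1e300. Evidence bands at 1/3 and 3 (annotations at 20 and 150).
  Worked examples recomputed from published summary statistics agree to
  printed precision once the 2-dp rounding of the printed t statistic is
  taken into account.

# Problem sizes used by the test suite

The simulation-based checks run at a documented demo scale chosen as the
package's own trade-off between statistical resolution and a practical
single-CPU runtime: family-wise-error calibration uses 200 independent
null experiments of 10 subjects × 16 channels × 126 timepoints with 1000
sign flips each; architecture recovery uses 20 subjects, three 1400 ms
tasks at 250 Hz, generalization grids on a 20 ms step, and 1000 sign
flips; the frequency-domain demos use 10 subjects. The analysis scripts
under `analysis/` default to 12 subjects at the full published epoch
windows. All of these scale up by changing one number in the respective
config.

# Known limitations and honest expectations

* With ~20 subjects, a two-sided JZS Bayes factor at prior scale
  $\sqrt{2}/2$ crosses BF01 = 3 only for |t| < 0.90, and under a true null
  P(|t₁₉| < 0.90) ≈ 0.62. "Substantial evidence for the null in ≥ 80% of
  cells", as reported for the 507-subject study, is therefore *not*
  attainable at demo scale in expectation — about two thirds of truly null
  cells is. The package reports the fraction as computed; readers should
  interpret BF01 maps at small n accordingly.
* The sign-flip test assumes symmetric subject-level accuracy
  distributions around their mean under the null; the Stelzer-style
  resampled null does not, which is why the scalar frequency-domain
  analysis uses it.
* TFCE cluster *extents* are descriptive (maximal runs of the significant
  mask); permutation correction controls the family-wise error of cell
  detection, not the precision of cluster boundaries.
* The EEGLAB importer reads the MATLAB v5 subset EEGLAB emits (numeric,
  char, cell, struct, zlib-compressed elements, `.fdt` companions),
  little-endian only; it is not a general MAT-file reader.
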