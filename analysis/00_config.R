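# Shared configuration for the analysis workflow.
#
# The study battery is emulated with four synthetic tasks at published
# trial-count / RT scales: a change-detection-like task (A) and a Stroop-
# naming-like task (C) share one fronto-central conflict pattern
# (overlap 1), a Simon-like task (B) carries an orthogonal pattern
# (overlap 0), and a Stroop-reading-like baseline (D) has no conflict
# signal at all. A weaker lateralized response-hand pattern is common to
# all tasks. Ground truth therefore is: within-task decoding in A, B, C;
# cross-task transfer only A<->C; hand decoding transfers everywhere.
#
# Every script regenerates the dataset deterministically from MASTER_SEED,
# so the scripts can be run independently and in any order (01 first is
# conventional, not required).

library(conflictMVPA)

MASTER_SEED <- 20260919L
RESULTS_DIR <- file.path("results")
LAMBDA <- 0.01
K_FOLDS <- 10
TIME_STEP <- 40        # ms grid for generalization matrices
N_ITER <- 1000         # sign-flip iterations for cluster correction
N_PERM <- 50           # label permutations per subject (frequency null)
N_DRAWS <- 10000       # resampled group null draws
CROSS_TASKS <- c("taskA_change", "taskB_simon", "taskC_naming")

demo_config <- function(seed = MASTER_SEED) {
  mk <- function(id, alpha, n_con, n_non, rt_con, rt_non, acc, window,
                 amp = 1.2, theta = 1) {
    task_recipe(id, epoch_window = window, n_conflict = n_con,
                n_nonconflict = n_non, evoked_amplitude = amp,
                evoked_latency = 400, evoked_width = 80,
                theta_amplitude = theta, overlap_alpha = alpha,
                motor_amplitude = 1.2, motor_window = c(300, 900),
                rt_model = list(conflict = lognormal_params(rt_con[1], rt_con[2]),
                                nonconflict = lognormal_params(rt_non[1], rt_non[2])),
                accuracy_rates = c(conflict = acc[1], nonconflict = acc[2]))
  }
  synth_config(
    tasks = list(
      mk("taskA_change", 1, 76, 163, c(534, 121), c(489, 107), c(0.68, 0.87),
         c(-500, 2800)),
      mk("taskB_simon", 0, 120, 120, c(603, 97), c(589, 95), c(0.91, 0.95),
         c(-500, 2500)),
      mk("taskC_naming", 1, 52, 52, c(1915, 461), c(1564, 370), c(0.93, 0.97),
         c(-400, 2000)),
      mk("taskD_reading", 0, 52, 52, c(1572, 264), c(1518, 275), c(0.97, 0.97),
         c(-400, 2000), amp = 0, theta = 0)),
    n_subjects = 12, seed = seed)
}

load_dataset <- function() generate_dataset(demo_config())

ensure_results <- function() dir.create(RESULTS_DIR, showWarnings = FALSE)
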