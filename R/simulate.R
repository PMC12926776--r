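#' Task recipe for the synthetic EEG generator
#'
#' Describes one conflict task: epoch window, per-condition trial counts,
#' the conflict effect carried by (a) a transient evoked bump and (b) an
#' induced theta-band oscillation, the degree of spatial overlap with the
#' dataset-wide shared conflict template, and the behavioral (RT/accuracy)
#' model.
#'
#' The conflict effect's spatial pattern is
#' `alpha * shared + sqrt(1 - alpha^2) * unique`, where `shared` is the
#' dataset-wide template, `unique` is a task-specific unit-norm vector
#' orthogonal to it, and `alpha = overlap_alpha` in `[0, 1]`. `alpha = 1`
#' means the task expresses exactly the shared pattern (fully domain-general
#' signal); `alpha = 0` an orthogonal, task-specific one.
#'
#' @param task_id unique task name.
#' @param epoch_window `c(start, end)` ms relative to stimulus onset.
#' @param n_conflict,n_nonconflict trial counts (may be unequal, as in real
#'   conflict paradigms where conditions are not presented equally often).
#' @param evoked_amplitude evoked conflict effect peak amplitude (microvolt).
#' @param evoked_latency,evoked_width Gaussian bump center and SD (ms).
#' @param evoked_window optional `c(start, end)` ms; when given the evoked
#'   effect is a boxcar confined to this window instead of a Gaussian bump.
#' @param theta_amplitude induced theta oscillation amplitude (microvolt);
#'   random phase per trial, so invisible to trial-averaged ERPs but visible
#'   to spectral power features.
#' @param theta_band `c(lo, hi)` Hz of the induced oscillation (default 3-7).
#' @param overlap_alpha fraction of the effect pattern shared with the
#'   dataset template (see Details).
#' @param effect_pattern optional explicit unit-norm channel pattern,
#'   overriding the `overlap_alpha` construction.
#' @param motor_amplitude amplitude of a lateralized response-hand pattern
#'   (sign flips between left- and right-hand trials) present in *both*
#'   conditions; used for the response-hand control analyses.
#' @param motor_window `c(start, end)` ms gate of the motor pattern.
#' @param rt_model list with elements `conflict` and `nonconflict`, each
#'   `c(meanlog, sdlog)` of a lognormal RT distribution (ms).
#' @param accuracy_rates named vector `c(conflict=, nonconflict=)` of
#'   Bernoulli correctness probabilities.
#' @return list of class `task_recipe`.
#' @export
task_recipe <- function(task_id,
                        epoch_window = c(-500, 2800),
                        n_conflict = 76, n_nonconflict = 163,
                        evoked_amplitude = 1.2,
                        evoked_latency = 400, evoked_width = 80,
                        evoked_window = NULL,
                        theta_amplitude = 1.0, theta_band = c(3, 7),
                        overlap_alpha = 1,
                        effect_pattern = NULL,
                        motor_amplitude = 0, motor_window = c(300, 900),
                        rt_model = NULL,
                        accuracy_rates = c(conflict = 0.85, nonconflict = 0.95)) {
  if (n_conflict <= 0 || n_nonconflict <= 0)
    stopf("trial counts must be positive (got %d / %d)", n_conflict, n_nonconflict)
  check_scalar_number(overlap_alpha, "overlap_alpha", 0, 1)
  if (epoch_window[1] >= epoch_window[2]) stopf("invalid epoch_window")
  if (is.null(rt_model))
    rt_model <- list(conflict = lognormal_params(600, 150),
                     nonconflict = lognormal_params(520, 120))
  structure(list(task_id = task_id, epoch_window = epoch_window,
                 n_conflict = as.integer(n_conflict),
                 n_nonconflict = as.integer(n_nonconflict),
                 evoked_amplitude = evoked_amplitude,
                 evoked_latency = evoked_latency, evoked_width = evoked_width,
                 evoked_window = evoked_window,
                 theta_amplitude = theta_amplitude, theta_band = theta_band,
                 overlap_alpha = overlap_alpha, effect_pattern = effect_pattern,
                 motor_amplitude = motor_amplitude, motor_window = motor_window,
                 rt_model = rt_model, accuracy_rates = accuracy_rates),
            class = "task_recipe")
}

#' Lognormal parameters from a target mean and SD (ms)
#' @param mean,sd desired distribution mean and standard deviation.
#' @return `c(meanlog, sdlog)`.
#' @export
lognormal_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + sd^2 / mean^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Study-scale default task recipes
#'
#' Four recipes emulating the structure of a conflict battery: a change
#' detection task with strongly unequal condition counts, a Simon-like task
#' with many trials, a Stroop naming task with slow lognormal RTs and a
#' Stroop reading baseline with no planted conflict signal at all. Trial
#' counts, epoch windows, RT scales and accuracy rates follow the published
#' scale of such batteries; conflict RTs are slower and less accurate than
#' non-conflict RTs in every task that carries a signal.
#'
#' @param overlap named numeric vector of `overlap_alpha` per task.
#' @export
study_recipes <- function(overlap = c(change_detection = 1, simon = 0,
                                      stroop_naming = 1, stroop_reading = 0)) {
  list(
    task_recipe("change_detection", epoch_window = c(-500, 2800),
                n_conflict = 76, n_nonconflict = 163,
                overlap_alpha = overlap[["change_detection"]],
                rt_model = list(conflict = lognormal_params(534, 121),
                                nonconflict = lognormal_params(489, 107)),
                accuracy_rates = c(conflict = 0.68, nonconflict = 0.87)),
    task_recipe("simon", epoch_window = c(-500, 2500),
                n_conflict = 226, n_nonconflict = 229,
                overlap_alpha = overlap[["simon"]],
                rt_model = list(conflict = lognormal_params(603, 97),
                                nonconflict = lognormal_params(589, 95)),
                accuracy_rates = c(conflict = 0.91, nonconflict = 0.95)),
    task_recipe("stroop_naming", epoch_window = c(-400, 2000),
                n_conflict = 52, n_nonconflict = 52,
                overlap_alpha = overlap[["stroop_naming"]],
                rt_model = list(conflict = lognormal_params(1915, 461),
                                nonconflict = lognormal_params(1564, 370)),
                accuracy_rates = c(conflict = 0.93, nonconflict = 0.97)),
    task_recipe("stroop_reading", epoch_window = c(-400, 2000),
                n_conflict = 52, n_nonconflict = 52,
                evoked_amplitude = 0, theta_amplitude = 0,
                overlap_alpha = overlap[["stroop_reading"]],
                rt_model = list(conflict = lognormal_params(1572, 264),
                                nonconflict = lognormal_params(1518, 275)),
                accuracy_rates = c(conflict = 0.97, nonconflict = 0.97))
  )
}

#' Synthetic dataset configuration
#'
#' @param tasks list of [task_recipe] objects with unique task ids.
#' @param n_subjects number of simulated subjects (>= 1).
#' @param montage an [eeg_montage][montage]; default the shipped 28-channel cap.
#' @param sample_rate simulation sampling rate in Hz.
#' @param noise_alpha spectral exponent of the 1/f background noise
#'   (power ~ f^-alpha; 1 = pink noise).
#' @param noise_sd per-channel background noise SD (microvolt).
#' @param spatial_mixing channel-correlation strength in `[0, 1]`: 0 gives
#'   independent channels, larger values mix channels through a fixed random
#'   orthogonal matrix.
#' @param shared_pattern unit-norm channel vector used as the dataset-wide
#'   shared conflict template; default the fronto-central template.
#' @param seed master RNG seed; identical `(config, seed)` pairs give
#'   bit-identical datasets.
#' @export
synth_config <- function(tasks = study_recipes(), n_subjects = 20,
                         montage = default_montage(), sample_rate = 250,
                         noise_alpha = 1.0, noise_sd = 1.0,
                         spatial_mixing = 0.3, shared_pattern = NULL,
                         seed = 1L) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  check_scalar_number(spatial_mixing, "spatial_mixing", 0, 1)
  ids <- vapply(tasks, `[[`, character(1), "task_id")
  if (anyDuplicated(ids)) stopf("task ids must be unique")
  if (is.null(shared_pattern)) shared_pattern <- frontocentral_template(montage)
  shared_pattern <- unit_norm(shared_pattern)
  structure(list(tasks = tasks, n_subjects = as.integer(n_subjects),
                 montage = montage, sample_rate = sample_rate,
                 noise_alpha = noise_alpha, noise_sd = noise_sd,
                 spatial_mixing = spatial_mixing,
                 shared_pattern = shared_pattern, seed = as.integer(seed)),
            class = "synth_config")
}

# internal generators -------------------------------------------------------

# 1/f noise: frequency-domain construction with random phases; each channel
# is scaled to unit SD before mixing so noise_sd sets the final scale.
pink_noise <- function(n_samples, n_ch, fs, alpha) {
  nf <- (n_samples - 1L) %/% 2L
  amp <- ((1:nf) * fs / n_samples)^(-alpha / 2)
  ph <- matrix(stats::runif(nf * n_ch, 0, 2 * pi), nf, n_ch)
  pos <- matrix(complex(modulus = rep(amp, n_ch), argument = as.vector(ph)),
                nf, n_ch)
  spec <- matrix(0 + 0i, n_samples, n_ch)
  spec[2:(nf + 1L), ] <- pos
  spec[n_samples:(n_samples - nf + 1L), ] <- Conj(pos)
  if (n_samples %% 2L == 0L)  # Nyquist bin, real-valued
    spec[nf + 2L, ] <- complex(real = amp[nf] * sign(stats::runif(n_ch) - 0.5))
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samples
  scale(x, center = TRUE, scale = apply(x, 2, stats::sd))
}

# fixed row-normalized mixing matrix A = (1-s) I + s Q, Q random orthogonal
mixing_matrix <- function(n_ch, s, seed) {
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_ch^2), n_ch)))
    A <- (1 - s) * diag(n_ch) + s * Q
    A / sqrt(rowSums(A^2))
  })
}

# lateralized motor template: x-weighted band around the central strip
motor_template <- function(m) {
  w <- m$positions[, 1] * exp(-m$positions[, 2]^2 / (2 * 0.3^2))
  unit_norm(w)
}

# resolve a recipe's effect pattern against the dataset's shared template
resolve_pattern <- function(recipe, shared, seed) {
  if (!is.null(recipe$effect_pattern)) return(unit_norm(recipe$effect_pattern))
  uniq <- with_seed(seed, stats::rnorm(length(shared)))
  uniq <- uniq - sum(uniq * shared) * shared
  uniq <- unit_norm(uniq)
  a <- recipe$overlap_alpha
  unit_norm(a * shared + sqrt(1 - a^2) * uniq)
}

generate_task_epochs <- function(recipe, config, subject_idx, pattern,
                                 mix, null_labels = FALSE) {
  fs <- config$sample_rate
  dt <- 1000 / fs
  t0 <- ceiling(recipe$epoch_window[1] / dt) * dt
  times <- seq(t0, recipe$epoch_window[2], by = dt)
  n_ti <- length(times)
  n_ch <- length(config$montage$labels)
  if (recipe$theta_amplitude > 0 &&
      (min(times) > 0 || max(times) < 1000))
    stopf("task '%s': epoch window must cover 0-1000 ms when theta effects are enabled",
          recipe$task_id)
  n_con <- recipe$n_conflict
  n_non <- recipe$n_nonconflict
  n_tr <- n_con + n_non
  cond <- rep(c("conflict", "nonconflict"), c(n_con, n_non))

  seed <- derive_seed(config$seed, "epochs", subject_idx, recipe$task_id)
  with_seed(seed, {
    # documented draw order: noise -> effect randomness (theta freq/phase)
    # -> response hand -> RT -> correctness
    dat <- array(0, c(n_tr, n_ch, n_ti))
    for (tr in seq_len(n_tr)) {
      noise <- pink_noise(n_ti, n_ch, fs, config$noise_alpha)   # samples x ch
      dat[tr, , ] <- config$noise_sd * (mix %*% t(noise))
    }

    # evoked conflict effect (deterministic time course, conflict trials only)
    bump <- if (!is.null(recipe$evoked_window)) {
      as.numeric(times >= recipe$evoked_window[1] & times <= recipe$evoked_window[2])
    } else {
      exp(-0.5 * ((times - recipe$evoked_latency) / recipe$evoked_width)^2)
    }
    theta_gate <- times >= 0 & times <= 1000
    conflict_idx <- which(cond == "conflict")
    th_f <- stats::runif(n_con, recipe$theta_band[1], recipe$theta_band[2])
    th_ph <- stats::runif(n_con, 0, 2 * pi)
    if (!null_labels && (recipe$evoked_amplitude != 0 || recipe$theta_amplitude != 0)) {
      for (j in seq_along(conflict_idx)) {
        tc <- recipe$evoked_amplitude * bump
        if (recipe$theta_amplitude != 0)
          tc <- tc + recipe$theta_amplitude * theta_gate *
            sin(2 * pi * th_f[j] * times / 1000 + th_ph[j])
        dat[conflict_idx[j], , ] <- dat[conflict_idx[j], , ] + outer(pattern, tc)
      }
    }

    hand <- sample(c("left", "right"), n_tr, replace = TRUE)
    if (recipe$motor_amplitude != 0) {
      mt <- motor_template(config$montage)
      gate <- as.numeric(times >= recipe$motor_window[1] &
                         times <= recipe$motor_window[2])
      sgn <- ifelse(hand == "right", 1, -1)
      for (tr in seq_len(n_tr))
        dat[tr, , ] <- dat[tr, , ] +
          recipe$motor_amplitude * sgn[tr] * outer(mt, gate)
    }

    rtp <- recipe$rt_model
    rt <- numeric(n_tr)
    rt[cond == "conflict"] <- stats::rlnorm(n_con, rtp$conflict[1], rtp$conflict[2])
    rt[cond == "nonconflict"] <- stats::rlnorm(n_non, rtp$nonconflict[1],
                                               rtp$nonconflict[2])
    acc <- recipe$accuracy_rates
    correct <- integer(n_tr)
    correct[cond == "conflict"] <- stats::rbinom(n_con, 1, acc[["conflict"]])
    correct[cond == "nonconflict"] <- stats::rbinom(n_non, 1, acc[["nonconflict"]])

    if (null_labels) cond <- sample(cond)  # labels independent of data

    epoch_set(dat, times, fs, config$montage$labels,
              data.frame(condition = cond, response_hand = hand,
                         rt_ms = rt, correct = correct,
                         stringsAsFactors = FALSE),
              subject_id = sprintf("s%02d", subject_idx),
              task_id = recipe$task_id)
  })
}

#' Generate a multi-subject, multi-task synthetic EEG dataset
#'
#' Each trial is 1/f background noise (spatially mixed across channels)
#' plus, on conflict trials, a transient evoked bump and an induced
#' theta-band oscillation with per-trial random phase, both projected on
#' the task's conflict pattern. RTs are lognormal and correctness Bernoulli
#' per condition. Identical `(config, seed)` pairs produce bit-identical
#' output.
#'
#' @param config a [synth_config].
#' @return list of class `synth_dataset`: `epochs` (list by subject of
#'   lists by task of [epoch_set]), `trial_table` (combined behavioral
#'   table) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_ch <- length(config$montage$labels)
  mix <- mixing_matrix(n_ch, config$spatial_mixing,
                       derive_seed(config$seed, "mixing"))
  patterns <- lapply(config$tasks, function(rec)
    resolve_pattern(rec, config$shared_pattern,
                    derive_seed(config$seed, "pattern", rec$task_id)))
  names(patterns) <- vapply(config$tasks, `[[`, character(1), "task_id")

  epochs <- vector("list", config$n_subjects)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    subj <- sprintf("s%02d", s)
    epochs[[s]] <- lapply(config$tasks, function(rec)
      generate_task_epochs(rec, config, s, patterns[[rec$task_id]], mix))
    names(epochs[[s]]) <- names(patterns)
    for (es in epochs[[s]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, task = es$task_id,
        trial = seq_len(nrow(es$trials)),
        es$trials, stringsAsFactors = FALSE)
    }
  }
  names(epochs) <- sprintf("s%02d", seq_len(config$n_subjects))
  structure(list(epochs = epochs, trial_table = do.call(rbind, rows),
                 patterns = patterns, config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d subjects x %d tasks (seed %d)\n",
              length(x$epochs), length(x$config$tasks), x$config$seed))
  invisible(x)
}

#' Generate a label-null epoch set
#'
#' Identical generative process for both conditions: effects are omitted
#' and condition labels are assigned independently of the data, for
#' type-I-error calibration of the decoding and inference stack.
#'
#' @param config a [synth_config] (its first task recipe provides the epoch
#'   geometry and behavioral model).
#' @param n_trials trials per condition (> 0).
#' @param subject_idx subject index entering the seed derivation.
#' @export
generate_null_dataset <- function(config, n_trials, subject_idx = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (n_trials <= 0) stopf("n_trials must be positive")
  rec <- config$tasks[[1]]
  rec$n_conflict <- as.integer(n_trials)
  rec$n_nonconflict <- as.integer(n_trials)
  rec$evoked_amplitude <- 0
  rec$theta_amplitude <- 0
  n_ch <- length(config$montage$labels)
  mix <- mixing_matrix(n_ch, config$spatial_mixing,
                       derive_seed(config$seed, "mixing"))
  generate_task_epochs(rec, config, subject_idx, config$shared_pattern, mix,
                       null_labels = TRUE)
}
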