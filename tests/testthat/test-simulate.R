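test_that("identical config and seed give bit-identical datasets", {
  cfg <- tiny_config(n_subjects = 2, seed = 42, window = c(-100, 1100))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$epochs$s01$A$data, d2$epochs$s01$A$data)
  expect_identical(d1$epochs$s02$B$data, d2$epochs$s02$B$data)
  expect_identical(d1$trial_table, d2$trial_table)
})

test_that("generator contracts reject degenerate inputs", {
  expect_error(task_recipe("x", n_conflict = 0), "positive")
  expect_error(task_recipe("x", overlap_alpha = 1.5), "outside")
  # epoch window excluding 0-1000 ms with theta enabled
  cfg <- synth_config(tasks = list(
    task_recipe("x", epoch_window = c(-200, 500), theta_amplitude = 1)),
    n_subjects = 1, seed = 1)
  expect_error(generate_dataset(cfg), "0-1000 ms")
  expect_error(generate_null_dataset(tiny_config(), 0), "positive")
  expect_error(synth_config(tasks = list(task_recipe("x"), task_recipe("x"))),
               "unique")
})

test_that("null datasets are reproducible and label-independent", {
  cfg <- tiny_config(seed = 5, window = c(-100, 500), theta = 0)
  cfg$tasks[[1]]$theta_amplitude <- 0
  a <- generate_null_dataset(cfg, 20)
  b <- generate_null_dataset(cfg, 20)
  expect_identical(a$data, b$data)
  expect_identical(a$trials$condition, b$trials$condition)
  expect_equal(sum(a$trials$condition == "conflict"), 20)
})

test_that("trial-averaged conflict difference projected on the pattern recovers the bump amplitude", {
  amp <- 1.4
  cfg <- synth_config(tasks = list(
    task_recipe("A", epoch_window = c(-100, 1100), n_conflict = 250,
                n_nonconflict = 250, evoked_amplitude = amp,
                evoked_latency = 400, evoked_width = 80,
                theta_amplitude = 1, overlap_alpha = 1)),
    n_subjects = 1, seed = 9)
  ds <- generate_dataset(cfg)
  es <- ds$epochs$s01$A
  pat <- ds$patterns$A
  pk <- which.min(abs(es$times - 400))
  con <- es$trials$condition == "conflict"
  proj <- apply(es$data[, , pk], 1, function(x) sum(x * pat))
  diff_mean <- mean(proj[con]) - mean(proj[!con])
  se <- sqrt(var(proj[con]) / sum(con) + var(proj[!con]) / sum(!con))
  expect_lt(abs(diff_mean - amp), 3 * se)
})

test_that("induced theta is invisible to the trial-averaged ERP", {
  cfg <- synth_config(tasks = list(
    task_recipe("A", epoch_window = c(-100, 1100), n_conflict = 200,
                n_nonconflict = 200, evoked_amplitude = 0,
                theta_amplitude = 2, overlap_alpha = 1)),
    n_subjects = 1, seed = 3)
  ds <- generate_dataset(cfg)
  es <- ds$epochs$s01$A
  pat <- ds$patterns$A
  con <- es$trials$condition == "conflict"
  idx <- es$times >= 0 & es$times <= 1000
  erp_diff <- apply(es$data[con, , idx], c(2, 3), mean) -
    apply(es$data[!con, , idx], c(2, 3), mean)
  proj <- colSums(erp_diff * pat)
  # random phase: mean projected difference stays at noise level << amplitude
  expect_lt(max(abs(proj)), 0.5)
})

test_that("noise-only channels follow the configured 1/f slope within 0.2", {
  for (alpha in c(0.5, 1)) {
    cfg <- synth_config(tasks = list(
      task_recipe("A", epoch_window = c(0, 4000), n_conflict = 30,
                  n_nonconflict = 30, evoked_amplitude = 0,
                  theta_amplitude = 0)),
      n_subjects = 1, noise_alpha = alpha, spatial_mixing = 0,
      seed = 21)
    es <- generate_dataset(cfg)$epochs$s01$A
    n <- dim(es$data)[3]
    freqs <- (seq_len(n) - 1) * es$sample_rate / n
    keep <- freqs >= 2 & freqs <= 40
    # average power spectrum over trials and channels
    pw <- 0
    for (ch in 1:4) {
      seg <- t(es$data[, ch, ])
      pw <- pw + rowMeans(Mod(stats::mvfft(seg))^2)
    }
    fit <- stats::lm(log(pw[keep]) ~ log(freqs[keep]))
    expect_lt(abs(-coef(fit)[2] - alpha), 0.2)
  }
})

test_that("decoding accuracy is non-decreasing in evoked amplitude", {
  amps <- c(0, 0.8, 1.6, 3)
  peak_acc <- matrix(NA_real_, 6, length(amps))
  for (s in 1:6) {
    for (j in seq_along(amps)) {
      cfg <- synth_config(tasks = list(
        task_recipe("A", epoch_window = c(200, 600), n_conflict = 25,
                    n_nonconflict = 25, evoked_amplitude = amps[j],
                    evoked_latency = 400, theta_amplitude = 0)),
        n_subjects = 1, seed = 100 + s)
      es <- generate_dataset(cfg)$epochs$s01$A
      m <- decode_timecourse(es, k = 5, seed = s)
      win <- abs(m$axes$time - 400) <= 100
      peak_acc[s, j] <- mean(m$values[win])
    }
  }
  means <- colMeans(peak_acc)
  expect_true(all(diff(means) > -0.01))
  expect_gt(means[length(amps)], means[1] + 0.1)
})

test_that("behavioral draws follow the configured conditional models", {
  cfg <- tiny_config(n_subjects = 1, seed = 8, n_con = 300, n_non = 300)
  tt <- generate_dataset(cfg)$trial_table
  a <- tt[tt$task == "A", ]
  expect_gt(mean(a$rt_ms[a$condition == "conflict"]),
            mean(a$rt_ms[a$condition == "nonconflict"]))
  expect_lt(mean(a$correct[a$condition == "conflict"]),
            mean(a$correct[a$condition == "nonconflict"]))
  # lognormal parameter mapping reproduces the target mean/sd
  p <- lognormal_params(534, 121)
  x <- exp(p[1] + p[2]^2 / 2)
  expect_equal(unname(x), 534, tolerance = 1e-10)
})

test_that("cross-task pattern geometry follows overlap_alpha", {
  cfg0 <- tiny_config(alpha_b = 0, seed = 2)
  ds0 <- generate_dataset(cfg0)
  expect_lt(abs(sum(ds0$patterns$A * ds0$patterns$B)), 1e-10)
  cfg1 <- tiny_config(alpha_b = 1, seed = 2)
  ds1 <- generate_dataset(cfg1)
  expect_equal(sum(ds1$patterns$A * ds1$patterns$B), 1, tolerance = 1e-10)
  expect_equal(sum(ds1$patterns$A^2), 1, tolerance = 1e-12)
})
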