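test_that("timecourse decoding is flat at chance on null data and flat above chance for a constant pattern", {
  # label-null data
  cfg <- tiny_config(seed = 13, window = c(-100, 500), theta = 0)
  cfg$tasks[[1]]$theta_amplitude <- 0
  nul <- generate_null_dataset(cfg, 25)
  m0 <- decode_timecourse(nul, k = 5, seed = 1)
  expect_lt(abs(mean(m0$values) - 0.5), 0.03)

  # time-constant planted pattern at high SNR: near-flat, above-chance profile
  pat <- unit_norm(c(1, 1, rep(0, 6)))
  es <- make_epochs(n_con = 60, n_non = 60, n_ch = 8, pattern = pat,
                    effect = 6, seed = 21)
  m1 <- decode_timecourse(es, k = 5, seed = 2)
  expect_gt(min(m1$values), 0.9)
  expect_lt(max(m1$values) - min(m1$values), 0.05)
})

# frequency analyses need epochs covering 0-1000 ms
crop_pad <- function(es) {
  make_epochs(n_con = 20, n_non = 20, n_ch = dim(es$data)[2],
              times = seq(0, 1096, 4), seed = 5)
}

test_that("maps are reproducible bit-exactly under a fixed seed", {
  es <- make_epochs(n_con = 20, n_non = 20, seed = 3)
  expect_identical(decode_timecourse(es, k = 5, seed = 7)$values,
                   decode_timecourse(es, k = 5, seed = 7)$values)
  expect_identical(as.numeric(decode_frequency(crop_pad(es), k = 5, seed = 7)),
                   as.numeric(decode_frequency(crop_pad(es), k = 5, seed = 7)))
})

test_that("electrode searchlight localizes a single-channel effect and snaps report times", {
  pat <- c(rep(0, 4), 1, rep(0, 3))       # effect confined to channel 5
  bump <- exp(-0.5 * ((seq(0, 396, 4) - 200) / 40)^2)
  es <- make_epochs(n_con = 40, n_non = 40, n_ch = 8, pattern = pat,
                    effect = 3 * bump, seed = 6)
  sl <- searchlight_time(es, k = 5, seed = 1)
  peak <- arrayInd(which.max(sl$values), dim(sl$values))
  expect_equal(peak[1], 5)                               # channel 5
  expect_lt(abs(sl$axes$time[peak[2]] - 200), 60)        # near effect latency

  maps <- report_timepoints(sl, times = c(252))
  expect_identical(colnames(maps), "252")                # on-grid, no snap
  expect_message(report_timepoints(sl, times = c(251)), "snapped")

  # null data: all cells near chance
  es0 <- make_epochs(n_con = 40, n_non = 40, n_ch = 8, seed = 7)
  sl0 <- searchlight_time(es0, k = 5, seed = 1)
  expect_lt(abs(mean(sl0$values) - 0.5), 0.02)
})

test_that("spectral features: on-bin tone concentration, zero input, and Parseval consistency", {
  fs <- 250
  times <- seq(0, 1096, 4)
  n_ti <- length(times)
  tone <- sin(2 * pi * 5 * times / 1000)
  dat <- array(0, c(2, 1, n_ti))
  dat[1, 1, ] <- tone
  es <- epoch_set(dat, times, fs, "ch1",
                  data.frame(condition = c("conflict", "nonconflict"),
                             response_hand = "left", rt_ms = 300, correct = 1))
  X <- fft_power_features(es, frequency_config())
  freqs <- attr(X, "freqs")
  expect_equal(freqs, 1:50)
  expect_equal(unname(which.max(X[1, ])), which(freqs == 5))
  off <- setdiff(seq_along(freqs), which(abs(freqs - 5) <= 1))
  expect_lt(max(X[1, off]) / max(X[1, ]), 0.01)
  expect_true(all(X[2, ] == 0))                          # zero signal

  # Parseval: retained bins + DC + Nyquist + mirror = N * time-domain energy
  set.seed(4)
  wn <- rnorm(250)
  dat2 <- array(wn, c(1, 1, n_ti))
  dat2[1, 1, ] <- c(wn, rep(0, n_ti - 250))
  es2 <- epoch_set(dat2, times, fs, "ch1",
                   data.frame(condition = "conflict", response_hand = "left",
                              rt_ms = 300, correct = 1))
  Xf <- fft_power_features(es2, frequency_config(freq_range = c(1, 124)))
  spec <- fft(wn)
  total <- 2 * sum(Xf[1, ]) + Mod(spec[1])^2 + Mod(spec[126])^2
  expect_equal(total, 250 * sum(wn^2), tolerance = 1e-6)
})

test_that("induced theta decodes in the frequency domain while the ERP stays flat", {
  cfg <- synth_config(tasks = list(
    task_recipe("A", epoch_window = c(-100, 1100), n_conflict = 50,
                n_nonconflict = 50, evoked_amplitude = 0,
                theta_amplitude = 1.5, overlap_alpha = 1)),
    n_subjects = 1, seed = 17)
  ds <- generate_dataset(cfg)
  es <- ds$epochs$s01$A
  acc_f <- as.numeric(decode_frequency(es, k = 5, seed = 2))
  expect_gt(acc_f, 0.6)
  acc_t <- decode_timecourse(es, k = 5, seed = 2)
  expect_lt(abs(mean(acc_t$values) - 0.5), 0.05)  # linear time-domain readout blind to phase-random theta
})

test_that("frequency searchlight finds the planted band and the single-cell effect", {
  cfg <- synth_config(tasks = list(
    task_recipe("A", epoch_window = c(-100, 1100), n_conflict = 60,
                n_nonconflict = 60, evoked_amplitude = 0,
                theta_amplitude = 1.5, theta_band = c(3, 7),
                overlap_alpha = 1)),
    n_subjects = 1, seed = 19)
  es <- generate_dataset(cfg)$epochs$s01$A
  sf <- searchlight_frequency(es, k = 5, seed = 3)
  peak_f <- sf$profile$frequency[which.max(sf$profile$accuracy)]
  expect_true(peak_f >= 3 && peak_f <= 7)
  expect_identical(unname(dim(sf$map$values)),
                   c(length(es$channels), nrow(sf$profile)))

  # effect on exactly one (channel, frequency) cell
  times <- seq(0, 1096, 4)
  set.seed(23)
  n_tr <- 80
  dat <- array(rnorm(n_tr * 4 * length(times)), c(n_tr, 4, length(times)))
  cond <- rep(c("conflict", "nonconflict"), each = n_tr / 2)
  for (tr in which(cond == "conflict"))
    dat[tr, 2, ] <- dat[tr, 2, ] +
      3 * sin(2 * pi * 10 * times / 1000 + runif(1, 0, 2 * pi))
  es2 <- epoch_set(dat, times, 250, paste0("ch", 1:4),
                   data.frame(condition = cond, response_hand = "left",
                              rt_ms = 300, correct = 1))
  sf2 <- searchlight_frequency(es2, k = 5, seed = 4)
  cell <- arrayInd(which.max(sf2$map$values), dim(sf2$map$values))
  expect_equal(cell[1], 2)
  expect_equal(sf2$map$axes$frequency[cell[2]], 10)
})

test_that("channel-averaged searchlight profile tracks full-feature per-bin decoding", {
  # averaged over subjects so the 40+ signal-free bins, where both
  # measures are independent noise, do not drown the rank agreement
  cfg <- synth_config(tasks = list(
    task_recipe("A", epoch_window = c(-100, 1100), n_conflict = 70,
                n_nonconflict = 70, evoked_amplitude = 0,
                theta_amplitude = 2, overlap_alpha = 1)),
    n_subjects = 4, seed = 29)
  ds <- generate_dataset(cfg)
  prof <- 0
  full <- 0
  for (s in names(ds$epochs)) {
    es <- ds$epochs[[s]]$A
    sf <- searchlight_frequency(es, k = 5, seed = 5)
    prof <- prof + sf$profile$accuracy
    X <- fft_power_features(es, frequency_config())
    nb <- length(attr(X, "freqs"))
    part <- balanced_partition(es$trials$condition, k = 5, seed = 5)
    full <- full + vapply(seq_len(nb), function(b) {
      cols <- (seq_along(es$channels) - 1) * nb + b   # all channels, one bin
      cv_accuracy(X[, cols, drop = FALSE], es$trials$condition, part,
                  zscore = TRUE)
    }, 0.0)
  }
  expect_gt(cor(prof, full, method = "spearman"), 0.5)
})

test_that("frequency decoding respects the z-transform mode and window contracts", {
  es <- make_epochs(n_con = 20, n_non = 20, times = seq(0, 1096, 4), seed = 8)
  expect_error(fft_power_features(
    make_epochs(times = seq(0, 396, 4)), frequency_config()), "cover")
  a_fold <- as.numeric(decode_frequency(es, k = 5, seed = 1))
  a_glob <- as.numeric(decode_frequency(es,
    frequency_config(z_transform = "global"), k = 5, seed = 1))
  expect_true(is.finite(a_fold) && is.finite(a_glob))
})
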