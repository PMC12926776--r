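# helper: epoch set holding a single deterministic signal on one channel
signal_epochs <- function(x, fs) {
  n <- length(x)
  epoch_set(array(x, c(1, 1, n)), seq(0, by = 1000 / fs, length.out = n),
            fs, "ch1",
            data.frame(condition = "conflict", response_hand = "left",
                       rt_ms = 300, correct = 1))
}

test_that("high-pass rejects DC and the passband preserves a 5 Hz tone", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)[-1]
  dc <- signal_epochs(rep(1, length(t)), fs)
  out <- fir_filter(dc, hp_cutoff = 0.5, lp_cutoff = 100)
  mid <- seq(round(length(t) * 0.4), round(length(t) * 0.6))
  expect_lt(max(abs(out$data[1, 1, mid])), 0.1)  # >= 20 dB attenuation

  tone <- signal_epochs(sin(2 * pi * 5 * t), fs)
  outt <- fir_filter(tone, hp_cutoff = 0.5, lp_cutoff = 100)
  amp <- max(abs(outt$data[1, 1, mid]))
  expect_lt(abs(amp - 1), 0.01)
})

test_that("stopband attenuation matches the DFT of the designed kernel", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)[-1]
  f0 <- 120
  tone <- signal_epochs(sin(2 * pi * f0 * t), fs)
  out <- fir_filter(tone, hp_cutoff = NULL, lp_cutoff = 100)
  # oracle: frequency response of the kernel evaluated by direct DFT
  k <- fir_kernel(fs, 100, type = "low")
  Hf <- abs(sum(k * exp(-2i * pi * f0 * (seq_along(k) - 1) / fs)))
  mid <- seq(round(length(t) * 0.4), round(length(t) * 0.6))
  y <- out$data[1, 1, mid]
  # measured amplitude via least squares on a sin/cos basis
  B <- cbind(sin(2 * pi * f0 * t[mid]), cos(2 * pi * f0 * t[mid]))
  amp <- sqrt(sum(stats::lm.fit(B, y)$coefficients^2))
  expect_lt(abs(amp - Hf), 1e-6)
})

test_that("FIR contracts: Nyquist violations are named", {
  es <- signal_epochs(rnorm(100), 250)
  expect_error(fir_filter(es, lp_cutoff = 130), "Nyquist")
  expect_error(fir_kernel(250, 130, 2, "low"), "Nyquist")
})

test_that("decimation keeps every k-th sample, retains t = 0 and rejects non-integer factors", {
  fs <- 1000
  times <- seq(-500, 998, by = 1)
  n <- length(times)
  dat <- array(rnorm(2 * 3 * n), c(2, 3, n))
  es <- epoch_set(dat, times, fs, c("a", "b", "c"),
                  data.frame(condition = c("conflict", "nonconflict"),
                             response_hand = "left", rt_ms = 300, correct = 1))
  out <- downsample(es, 250)
  expect_equal(out$sample_rate, 250)
  expect_true(0 %in% out$times)
  expect_equal(diff(out$times)[1], 4)
  keep <- which(times %in% out$times)
  expect_identical(out$data, es$data[, , keep, drop = FALSE])
  expect_identical(downsample(es, 1000), es)      # identity
  expect_error(downsample(es, 300), "integer")
})

test_that("baseline correction zeroes the window mean, is idempotent and offset-equivariant", {
  es <- make_epochs(n_con = 5, n_non = 5, n_ch = 3, times = seq(-100, 396, 4))
  out <- baseline_correct(es, c(0, 200))
  idx <- out$times >= 0 & out$times <= 200
  base <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-10)
  again <- baseline_correct(out, c(0, 200))
  expect_equal(again$data, out$data, tolerance = 1e-12)
  # constant offset on one channel disappears entirely
  shifted <- es
  shifted$data[, 2, ] <- shifted$data[, 2, ] + 7.3
  out2 <- baseline_correct(shifted, c(0, 200))
  expect_equal(out2$data[, 2, ], out$data[, 2, ], tolerance = 1e-10)
  expect_error(baseline_correct(es, c(900, 950)), "no samples")
})

test_that("channel harmonization reduces to the sorted intersection", {
  mk <- function(chs) {
    n <- length(chs)
    epoch_set(array(seq_len(2 * n * 3), c(2, n, 3)), c(0, 4, 8), 250, chs,
              data.frame(condition = c("conflict", "nonconflict"),
                         response_hand = "left", rt_ms = 300, correct = 1))
  }
  a <- mk(c("Fz", "Cz", "Pz"))
  b <- mk(c("Cz", "Pz", "Oz"))
  out <- harmonize_channels(list(a, b))
  expect_identical(out[[1]]$channels, c("Cz", "Pz"))
  expect_identical(out[[2]]$channels, c("Cz", "Pz"))
  expect_identical(out[[1]]$data[, 1, ], a$data[, 2, ])  # Cz moved first
  same <- harmonize_channels(list(a, a))
  expect_identical(same[[1]]$channels, sort(a$channels))
  expect_error(harmonize_channels(list(a, mk(c("X1", "X2", "X3")))), "empty")
})

test_that("trial screening applies task ceilings, premature and response rules in order", {
  es <- make_epochs(n_con = 2, n_non = 1, n_ch = 2, task_id = "simon")
  es$trials$rt_ms <- c(300, 1499, 1501)
  out <- screen_trials(es, screening_rules())
  expect_equal(dim(out$epochs$data)[1], 2)
  expect_equal(out$report$dropped[out$report$reason == "too_slow"], 1L)
  expect_identical(out$epochs$trials$rt_ms, c(300, 1499))  # order preserved

  es$trials$rt_ms <- c(50, 150, 400)
  out2 <- screen_trials(es, screening_rules())
  expect_equal(out2$report$dropped[out2$report$reason == "premature"], 1L)

  es$trials$rt_ms <- c(300, 400, 500)
  out3 <- screen_trials(es, screening_rules())
  expect_equal(sum(out3$report$dropped), 0L)
  expect_identical(out3$epochs$data, es$data)

  es$trials$rt_ms <- c(NA, 400, 500)
  out4 <- screen_trials(es, screening_rules())
  expect_equal(out4$report$dropped[out4$report$reason == "no_response"], 1L)
  es$trials$correct <- c(1L, 0L, 1L)
  out5 <- screen_trials(es, screening_rules(correct_only = TRUE))
  expect_equal(out5$report$dropped[out5$report$reason == "incorrect"], 1L)
})

test_that("preprocessing is pure and the canonical chain composes", {
  cfg <- tiny_config(seed = 31, window = c(-400, 1200), theta = 0)
  cfg$tasks[[1]]$theta_amplitude <- 0
  cfg$sample_rate <- 500
  es <- generate_dataset(cfg)$epochs$s01$A
  snapshot <- es$data + 0
  pc <- preprocess_config(hp_cutoff = 0.5, lp_cutoff = 100, target_rate = 250,
                          baseline_window = c(0, 200),
                          screening = screening_rules(rt_max = c(default = 1500)))
  out <- preprocess(es, pc)
  expect_identical(es$data, snapshot)           # input untouched
  expect_equal(out$sample_rate, 250)
  idx <- out$times >= 0 & out$times <= 200
  expect_lt(max(abs(apply(out$data[, , idx], c(1, 2), mean))), 1e-9)
  expect_false(is.null(attr(out, "provenance")))
  expect_error(preprocess_config(hp_cutoff = 0), "hp_cutoff")
})
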