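#' Decoding map container
#'
#' Accuracy values on a named grid: `time` (timecourse), `channel` x `time`
#' (electrode searchlight), `channel` x `frequency` (spectral searchlight),
#' or `train_time` x `test_time` (temporal generalization). One layer per
#' subject; single-subject analyses return a single layer.
#'
#' @param values numeric vector/matrix/array matching the axis lengths.
#' @param axes named list of axis coordinate vectors, in dimension order.
#' @param meta named list of provenance fields (subject, task, label type,
#'   lambda, seed, ...).
#' @export
decoding_map <- function(values, axes, meta = list()) {
  dims <- vapply(axes, length, 0L)
  values <- if (length(dims) == 1L) as.numeric(values) else
    array(values, dims)
  if (length(values) != prod(dims))
    stopf("values length %d does not match grid size %d",
          length(values), prod(dims))
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stopf("accuracies must lie in [0, 1]")
  structure(list(values = values, axes = axes, chance = 0.5, meta = meta),
            class = "decoding_map")
}

#' @export
print.decoding_map <- function(x, ...) {
  cat(sprintf("<decoding_map> %s grid (%s); mean accuracy %.3f (chance %.2f)\n",
              paste(names(x$axes), collapse = " x "),
              paste(vapply(x$axes, length, 0L), collapse = " x "),
              mean(x$values), x$chance))
  invisible(x)
}

# label selection: condition (conflict decoding) or response_hand (control)
select_label <- function(epochs, label = c("condition", "response_hand")) {
  label <- match.arg(label)
  if (label == "condition")
    return(list(epochs = epochs, y = epochs$trials$condition))
  keep <- epochs$trials$response_hand %in% c("left", "right")
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$trials <- epochs$trials[keep, , drop = FALSE]
  list(epochs = out, y = out$trials$response_hand)
}

map_meta <- function(epochs, label, lambda, seed, extra = list()) {
  c(list(subject = epochs$subject_id, task = epochs$task_id,
         label_type = label, lambda = lambda, seed = seed,
         chance = 0.5), extra)
}

#' Time-resolved within-task decoding
#'
#' At every timepoint the classifier uses all channels' amplitudes as
#' features and is scored by balanced k-fold cross-validation. One
#' partition is drawn per subject and reused across all timepoints, so
#' timepoints differ only in their features, never in their fold
#' assignment.
#'
#' @param epochs an [epoch_set] (screened).
#' @param lambda LDA shrinkage.
#' @param k,n_repeats,seed passed to [balanced_partition].
#' @param label decode the conflict condition (default) or response hand.
#' @return a [decoding_map] on the epoch's time axis.
#' @export
decode_timecourse <- function(epochs, lambda = 0.01, k = 10, n_repeats = 1,
                              seed = 1L, label = "condition") {
  sel <- select_label(epochs, label)
  part <- balanced_partition(sel$y, k, n_repeats, seed)
  y01 <- label01(sel$y, part$classes)
  acc <- decode_timecourse_cpp(sel$epochs$data, y01, part$repeats, lambda)
  decoding_map(acc, list(time = epochs$times),
               map_meta(epochs, label, lambda, seed))
}

#' Electrode-by-timepoint searchlight decoding
#'
#' Single-feature decoding for every (channel, timepoint) cell (for one
#' feature the shrinkage target is proportional to the pooled variance, so
#' `lambda` does not affect predictions). Use [report_timepoints] to pull
#' topographic maps at key latencies.
#'
#' @inheritParams decode_timecourse
#' @return a [decoding_map] on the channel x time grid.
#' @export
searchlight_time <- function(epochs, k = 10, n_repeats = 1, seed = 1L,
                             label = "condition") {
  sel <- select_label(epochs, label)
  part <- balanced_partition(sel$y, k, n_repeats, seed)
  y01 <- label01(sel$y, part$classes)
  d <- dim(sel$epochs$data)
  X <- matrix(sel$epochs$data, d[1], d[2] * d[3])
  acc <- searchlight_map_cpp(X, y01, part$repeats)
  decoding_map(acc, list(channel = epochs$channels, time = epochs$times),
               map_meta(epochs, label, NA_real_, seed))
}

#' Extract topographies at requested timepoints
#'
#' Requested times off the sample grid are snapped to the nearest sample
#' (reported via a message).
#'
#' @param map a channel x time [decoding_map].
#' @param times requested timepoints (ms); defaults to the canonical report
#'   latencies 252, 500, 752, 1000 and 1500 ms.
#' @return matrix channels x requested times.
#' @export
report_timepoints <- function(map, times = c(252, 500, 752, 1000, 1500)) {
  stopifnot(identical(names(map$axes), c("channel", "time")))
  grid <- map$axes$time
  idx <- vapply(times, function(t) which.min(abs(grid - t)), 0L)
  snapped <- grid[idx]
  if (any(abs(snapped - times) > 1e-9))
    message(sprintf("report times snapped to grid: %s",
                    paste(sprintf("%g->%g", times[snapped != times],
                                  snapped[snapped != times]), collapse = ", ")))
  out <- map$values[, idx, drop = FALSE]
  dimnames(out) <- list(map$axes$channel, snapped)
  out
}

#' Frequency-domain feature configuration
#'
#' @param window analysis window `c(start, end)` ms; treated half-open
#'   `[start, end)` on the sample grid so a 1000 ms window at 250 Hz yields
#'   250 samples and exact 1 Hz DFT bins.
#' @param freq_range `c(lo, hi)` Hz of retained bins (within (0, Nyquist)).
#' @param taper `"none"` (bare DFT, the default) or `"hann"`.
#' @param z_transform `"foldwise"` (z-scoring fitted on each training fold,
#'   leakage-free default) or `"global"` (one z-transform over all trials
#'   before cross-validation, for fidelity comparisons).
#' @export
frequency_config <- function(window = c(0, 1000), freq_range = c(1, 50),
                             taper = c("none", "hann"),
                             z_transform = c("foldwise", "global")) {
  structure(list(window = window, freq_range = freq_range,
                 taper = match.arg(taper),
                 z_transform = match.arg(z_transform)),
            class = "frequency_config")
}

#' Spectral power features
#'
#' Per trial and channel, the DFT of the analysis window; features are the
#' squared magnitudes of the bins inside `freq_range`, ordered
#' channel-major (all retained frequencies of channel 1, then channel 2,
#' ...). Attributes `channels` and `freqs` describe the feature axis.
#'
#' @param epochs an [epoch_set] whose epoch covers the window.
#' @param fconfig a [frequency_config].
#' @return trials x (channels * bins) feature matrix.
#' @export
fft_power_features <- function(epochs, fconfig = frequency_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sample_rate
  n <- round((fconfig$window[2] - fconfig$window[1]) / 1000 * fs)
  start <- which(epochs$times >= fconfig$window[1] - 1e-9)[1]
  if (is.na(start) || start + n - 1 > length(epochs$times))
    stopf("epoch [%g, %g] ms does not cover the analysis window [%g, %g) ms",
          min(epochs$times), max(epochs$times),
          fconfig$window[1], fconfig$window[2])
  idx <- start:(start + n - 1)
  if (any(fconfig$freq_range <= 0) || any(fconfig$freq_range >= fs / 2))
    stopf("freq_range must lie strictly inside (0, %g) Hz", fs / 2)
  d <- dim(epochs$data)
  seg <- matrix(aperm(epochs$data[, , idx, drop = FALSE], c(3, 1, 2)),
                n, d[1] * d[2])            # time x (trial, channel)
  if (fconfig$taper == "hann") {
    h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    seg <- seg * h
  }
  pw <- Mod(stats::mvfft(seg))^2           # bins x (trial, channel)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- which(freqs >= fconfig$freq_range[1] - 1e-9 &
                freqs <= fconfig$freq_range[2] + 1e-9)
  nb <- length(keep)
  # -> trials x (channel-major features)
  arr <- array(t(pw[keep, , drop = FALSE]), c(d[1], d[2], nb))
  X <- matrix(0, d[1], nb * d[2])
  for (ch in seq_len(d[2]))
    X[, (ch - 1) * nb + seq_len(nb)] <- arr[, ch, ]
  structure(X, channels = epochs$channels, freqs = freqs[keep],
            provenance = "channel x frequency power")
}

#' Frequency-domain within-task decoding
#'
#' Balanced k-fold accuracy on [fft_power_features], with z-transformation
#' of every feature (fold-wise by default), yielding a single accuracy per
#' subject and task.
#'
#' @inheritParams decode_timecourse
#' @param fconfig a [frequency_config].
#' @return scalar accuracy with attribute `meta`.
#' @export
decode_frequency <- function(epochs, fconfig = frequency_config(),
                             lambda = 0.01, k = 10, n_repeats = 1,
                             seed = 1L, label = "condition") {
  sel <- select_label(epochs, label)
  X <- fft_power_features(sel$epochs, fconfig)
  part <- balanced_partition(sel$y, k, n_repeats, seed)
  if (fconfig$z_transform == "global") {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    acc <- cv_accuracy(X, sel$y, part, lambda, zscore = FALSE)
  } else {
    acc <- cv_accuracy(X, sel$y, part, lambda, zscore = TRUE)
  }
  structure(acc, meta = map_meta(epochs, label, lambda, seed,
                                 list(domain = "frequency")))
}

#' Electrode-by-frequency searchlight decoding
#'
#' Single-feature decoding per (channel, frequency bin) cell; also returns
#' the channel-averaged accuracy-by-frequency profile. Z-scoring is omitted
#' here because single-feature LDA predictions are invariant to per-feature
#' affine rescaling.
#'
#' @inheritParams decode_frequency
#' @param report_freqs key frequencies for topographic reporting.
#' @return list with `map` (channel x frequency [decoding_map]), `profile`
#'   (data.frame `frequency`, `accuracy`) and `report` (channels x
#'   report_freqs matrix).
#' @export
searchlight_frequency <- function(epochs, fconfig = frequency_config(),
                                  k = 10, n_repeats = 1, seed = 1L,
                                  label = "condition",
                                  report_freqs = c(3, 5, 7, 10, 15, 20, 25, 30)) {
  sel <- select_label(epochs, label)
  X <- fft_power_features(sel$epochs, fconfig)
  freqs <- attr(X, "freqs")
  part <- balanced_partition(sel$y, k, n_repeats, seed)
  y01 <- label01(sel$y, part$classes)
  acc <- searchlight_map_cpp(unclass(X), y01, part$repeats)
  nch <- length(epochs$channels)
  vals <- matrix(acc, nch, length(freqs), byrow = TRUE)  # features were channel-major
  map <- decoding_map(vals, list(channel = epochs$channels, frequency = freqs),
                      map_meta(epochs, label, NA_real_, seed,
                               list(domain = "frequency")))
  profile <- data.frame(frequency = freqs, accuracy = colMeans(vals))
  ridx <- vapply(report_freqs, function(f) which.min(abs(freqs - f)), 0L)
  report <- vals[, ridx, drop = FALSE]
  dimnames(report) <- list(epochs$channels, freqs[ridx])
  list(map = map, profile = profile, report = report)
}
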