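#' Preprocessing configuration
#'
#' Defaults follow minimal-preprocessing MVPA practice: Hamming windowed
#' sinc FIR band limits of 0.5-100 Hz (keeps theta through low gamma for
#' the 1-50 Hz spectral feature range), decimation to 250 Hz, and a
#' 0-200 ms post-stimulus baseline. The baseline window is configurable;
#' see the methods vignette for why the post-stimulus default is kept
#' literal.
#'
#' @param hp_cutoff,lp_cutoff high-/low-pass -6 dB cutoffs (Hz).
#' @param target_rate decimation target (Hz).
#' @param baseline_window `c(start, end)` ms, closed interval on the sample
#'   grid.
#' @param epoch_window optional named list of `c(start, end)` ms per task id
#'   used by [preprocess] to crop epochs.
#' @param screening optional [screening_rules].
#' @export
preprocess_config <- function(hp_cutoff = 0.5, lp_cutoff = 100,
                              target_rate = 250,
                              baseline_window = c(0, 200),
                              epoch_window = NULL, screening = NULL) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < target_rate / 2))
    stopf("need 0 < hp_cutoff (%g) < lp_cutoff (%g) < target_rate/2 (%g)",
          hp_cutoff, lp_cutoff, target_rate / 2)
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 target_rate = target_rate, baseline_window = baseline_window,
                 epoch_window = epoch_window, screening = screening),
            class = "preprocess_config")
}

# kernel design -------------------------------------------------------------
# Hamming windowed sinc FIR. Transition bandwidth rule (documented contract):
# transition = min(max(cutoff * 0.25, 2 Hz), cap), where the cap keeps the
# stopband edge inside the representable band: 2 * cutoff for a high-pass
# (stopband edge >= DC), fs/2 - cutoff for a low-pass (edge <= Nyquist).
# Kernel length = 3.3 / (transition / fs) rounded up to the next odd
# integer, the classic Hamming-window approximation for ~53 dB stopband
# attenuation.

#' Transition bandwidth of the package's FIR designs
#' @param cutoff -6 dB cutoff (Hz).
#' @param type `"low"` or `"high"`.
#' @param fs sampling rate (Hz).
#' @export
fir_transition <- function(cutoff, type = c("low", "high"), fs = 250) {
  type <- match.arg(type)
  cap <- if (type == "high") 2 * cutoff else fs / 2 - cutoff
  min(max(cutoff * 0.25, 2), cap)
}

#' Design the package's Hamming windowed sinc FIR kernel
#'
#' @param fs sampling rate (Hz).
#' @param cutoff -6 dB cutoff frequency (Hz).
#' @param transition transition bandwidth (Hz); defaults to
#'   [fir_transition].
#' @param type `"low"` or `"high"`.
#' @return numeric kernel of odd length (type-I linear phase).
#' @export
fir_kernel <- function(fs, cutoff, transition = NULL,
                       type = c("low", "high")) {
  type <- match.arg(type)
  if (is.null(transition)) transition <- fir_transition(cutoff, type, fs)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stopf("FIR %s-pass cutoff %g Hz violates the Nyquist limit %g Hz",
          type, cutoff, fs / 2)
  L <- ceiling(3.3 * fs / transition)
  if (L %% 2 == 0) L <- L + 1
  signal::fir1(L - 1, cutoff / (fs / 2), type = type)  # Hamming default
}

# zero-phase application: forward convolution with a symmetric kernel and
# group-delay trimming; edges are padded by replication to limit transients.
apply_fir <- function(X, kernel) {   # X: signals x time
  L <- length(kernel)
  half <- (L - 1L) %/% 2L
  n <- ncol(X)
  pad <- cbind(X[, rep(1L, half), drop = FALSE], X,
               X[, rep(n, half), drop = FALSE])
  nf <- stats::nextn(ncol(pad) + L - 1L, 2)
  K <- stats::fft(c(kernel, numeric(nf - L)))
  P <- t(stats::mvfft(t(cbind(pad, matrix(0, nrow(X), nf - ncol(pad))))))
  Y <- t(Re(stats::mvfft(t(P * rep(K, each = nrow(X))), inverse = TRUE))) / nf
  Y[, (2L * half + 1L):(2L * half + n), drop = FALSE]
}

#' FIR band-pass filter an epoch set
#'
#' Zero-phase application (forward pass of a linear-phase Hamming windowed
#' sinc kernel with group-delay compensation) of a high-pass and then a
#' low-pass kernel along the time axis of every trial and channel. Either
#' cutoff may be `NULL` to skip that stage. Returns a new `epoch_set`; the
#' input is not modified.
#'
#' @param epochs an [epoch_set].
#' @param hp_cutoff,lp_cutoff cutoffs in Hz.
#' @export
fir_filter <- function(epochs, hp_cutoff = 0.5, lp_cutoff = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sample_rate
  if (!is.null(lp_cutoff) && fs <= 2 * lp_cutoff)
    stopf("lp_cutoff %g Hz violates the Nyquist limit %g Hz", lp_cutoff, fs / 2)
  d <- dim(epochs$data)
  X <- matrix(epochs$data, d[1] * d[2], d[3])
  if (!is.null(hp_cutoff))
    X <- apply_fir(X, fir_kernel(fs, hp_cutoff, type = "high"))
  if (!is.null(lp_cutoff))
    X <- apply_fir(X, fir_kernel(fs, lp_cutoff, type = "low"))
  out <- epochs
  out$data <- array(X, d)
  out
}

#' Decimate an epoch set to a lower sampling rate
#'
#' Keeps every `factor`-th sample, aligned so that the sample at t = 0 ms
#' (or, when 0 is outside the epoch, the sample closest to 0) remains on the
#' grid. No anti-alias filter is applied here: the canonical chain (see
#' [preprocess]) low-pass filters below the target Nyquist first, which is a
#' precondition documented for calling this directly.
#'
#' @param epochs an [epoch_set].
#' @param target_rate new rate (Hz); the original rate must be an integer
#'   multiple.
#' @export
downsample <- function(epochs, target_rate) {
  stopifnot(inherits(epochs, "epoch_set"))
  ratio <- epochs$sample_rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("sample_rate %g is not an integer multiple of target %g Hz",
          epochs$sample_rate, target_rate)
  factor <- as.integer(round(ratio))
  if (factor == 1L) return(epochs)
  i0 <- which.min(abs(epochs$times))
  keep <- which((seq_along(epochs$times) - i0) %% factor == 0L)
  out <- epochs
  out$data <- epochs$data[, , keep, drop = FALSE]
  out$times <- epochs$times[keep]
  out$sample_rate <- target_rate
  out
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over samples with
#' `window[1] <= t <= window[2]` (closed interval on the sample grid).
#'
#' @param epochs an [epoch_set].
#' @param window `c(start, end)` ms.
#' @export
baseline_correct <- function(epochs, window = c(0, 200)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(idx))
    stopf("baseline window [%g, %g] ms contains no samples", window[1], window[2])
  out <- epochs
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  out$data <- epochs$data - array(base, dim(epochs$data))
  out
}

#' Crop an epoch set to a time window
#'
#' @param epochs an [epoch_set].
#' @param window `c(start, end)` ms, closed interval on the sample grid.
#' @export
crop_epochs <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(idx)) stopf("crop window [%g, %g] ms contains no samples",
                          window[1], window[2])
  out <- epochs
  out$data <- epochs$data[, , idx, drop = FALSE]
  out$times <- epochs$times[idx]
  out
}

#' Restrict epoch sets to their common electrodes
#'
#' Every set is reduced, in canonical (alphabetical) order, to the
#' intersection of all channel labels, mirroring the harmonization of
#' recordings made with different caps.
#'
#' @param epoch_sets list of [epoch_set] objects.
#' @return list of epoch sets on identical channel grids.
#' @export
harmonize_channels <- function(epoch_sets) {
  if (!length(epoch_sets)) stopf("need at least one epoch set")
  common <- Reduce(intersect, lapply(epoch_sets, `[[`, "channels"))
  if (!length(common)) stopf("channel intersection is empty")
  common <- sort(common)
  lapply(epoch_sets, function(es) {
    idx <- match(common, es$channels)
    out <- es
    out$data <- es$data[, idx, , drop = FALSE]
    out$channels <- common
    out
  })
}

#' Trial screening rules
#'
#' @param rt_max named vector of per-task RT ceilings (ms); entry `default`
#'   is used for tasks without their own ceiling. Defaults follow classic
#'   conflict-battery limits: 1800 ms change detection, 1500 ms Simon,
#'   4000 ms Stroop.
#' @param premature minimum valid RT in ms (default 100); faster responses
#'   are removed as premature.
#' @param require_response drop trials without a response (RT missing).
#' @param correct_only additionally drop incorrect trials (off by default;
#'   both modes are supported for decoding).
#' @export
screening_rules <- function(rt_max = c(change_detection = 1800, simon = 1500,
                                       stroop_naming = 4000,
                                       stroop_reading = 4000, default = 4000),
                            premature = 100, require_response = TRUE,
                            correct_only = FALSE) {
  if (any(rt_max <= premature))
    stopf("every rt_max must exceed the premature threshold (%g ms)", premature)
  structure(list(rt_max = rt_max, premature = premature,
                 require_response = require_response,
                 correct_only = correct_only),
            class = "screening_rules")
}

screen_reasons <- function(task, rt, correct, rules) {
  ceiling_ms <- rules$rt_max[[if (task %in% names(rules$rt_max)) task else "default"]]
  reason <- rep("retained", length(rt))
  if (rules$correct_only) reason[correct == 0] <- "incorrect"
  reason[rt > ceiling_ms] <- "too_slow"
  reason[!is.na(rt) & rt < rules$premature] <- "premature"
  if (rules$require_response) reason[is.na(rt)] <- "no_response"
  reason
}

#' Screen trials of an epoch set
#'
#' Drops trials with no response, premature responses, over-ceiling RTs and
#' (optionally) errors; retained trials keep their original order. The
#' report counts dropped trials per reason (a trial is counted once, under
#' the highest-priority reason: no response, premature, too slow,
#' incorrect).
#'
#' @param epochs an [epoch_set].
#' @param rules a [screening_rules].
#' @return list with elements `epochs` (screened set) and `report`
#'   (data.frame reason/count).
#' @export
screen_trials <- function(epochs, rules = screening_rules()) {
  stopifnot(inherits(epochs, "epoch_set"))
  reason <- screen_reasons(epochs$task_id, epochs$trials$rt_ms,
                           epochs$trials$correct, rules)
  keep <- reason == "retained"
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$trials <- epochs$trials[keep, , drop = FALSE]
  rownames(out$trials) <- NULL
  lv <- c("no_response", "premature", "too_slow", "incorrect")
  report <- data.frame(reason = lv,
                       dropped = as.integer(table(factor(reason, lv))),
                       stringsAsFactors = FALSE)
  if (!any(keep)) warning("screening removed every trial", call. = FALSE)
  list(epochs = out, report = report)
}

#' Screen a behavioral trial table
#'
#' Table analogue of [screen_trials], applied per task.
#' @param tab trial table with columns `task`, `rt_ms`, `correct`.
#' @param rules a [screening_rules].
#' @export
screen_trial_table <- function(tab, rules = screening_rules()) {
  reason <- character(nrow(tab))
  for (tk in unique(tab$task)) {
    ix <- which(tab$task == tk)
    reason[ix] <- screen_reasons(tk, tab$rt_ms[ix], tab$correct[ix], rules)
  }
  keep <- reason == "retained"
  lv <- c("no_response", "premature", "too_slow", "incorrect")
  report <- data.frame(reason = lv,
                       dropped = as.integer(table(factor(reason, lv))),
                       stringsAsFactors = FALSE)
  list(table = tab[keep, , drop = FALSE], report = report)
}

#' Canonical preprocessing chain
#'
#' Applies, in the documented order: FIR band-pass filter, decimation,
#' epoch cropping (when the config names a window for the task), baseline
#' removal, trial screening (when configured). All stages are pure; the
#' returned epoch set carries a `provenance` attribute recording parameters.
#'
#' @param epochs an [epoch_set].
#' @param config a [preprocess_config].
#' @return screened, preprocessed `epoch_set` (screening report, if any, in
#'   `attr(, "screening_report")`).
#' @export
preprocess <- function(epochs, config = preprocess_config()) {
  out <- fir_filter(epochs, config$hp_cutoff, config$lp_cutoff)
  out <- downsample(out, config$target_rate)
  win <- config$epoch_window[[epochs$task_id]]
  if (!is.null(win)) out <- crop_epochs(out, win)
  out <- baseline_correct(out, config$baseline_window)
  report <- NULL
  if (!is.null(config$screening)) {
    sc <- screen_trials(out, config$screening)
    out <- sc$epochs
    report <- sc$report
  }
  attr(out, "provenance") <- list(
    chain = c("fir_filter", "downsample", "crop", "baseline",
              if (!is.null(report)) "screen"),
    hp_cutoff = config$hp_cutoff, lp_cutoff = config$lp_cutoff,
    target_rate = config$target_rate, baseline_window = config$baseline_window)
  attr(out, "screening_report") <- report
  out
}
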