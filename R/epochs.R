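#' Epoched EEG data for one subject and one task
#'
#' The central container: a trials x channels x timepoints array of
#' amplitudes (microvolts) with per-trial annotations. Times are in
#' milliseconds relative to stimulus onset and must lie on a uniform grid
#' of spacing `1000 / sample_rate`.
#'
#' @param data numeric array, trials x channels x timepoints.
#' @param times numeric vector of sample times (ms), strictly increasing,
#'   uniformly spaced.
#' @param sample_rate sampling rate in Hz.
#' @param channels character vector of channel labels (length = dim 2).
#' @param trials data.frame with one row per trial and columns
#'   `condition` (`"conflict"` / `"nonconflict"`), `response_hand`
#'   (`"left"` / `"right"` / `"none"`), `rt_ms` (NA where no response) and
#'   `correct` (0/1).
#' @param subject_id,task_id identifiers carried through all downstream maps.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sample_rate, channels, trials,
                      subject_id = "s01", task_id = "task") {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stopf("`data` must be a 3-d array")
  if (dim(data)[2] != length(channels))
    stopf("channel dimension (%d) != number of labels (%d)",
          dim(data)[2], length(channels))
  if (dim(data)[3] != length(times))
    stopf("time dimension (%d) != length of `times` (%d)",
          dim(data)[3], length(times))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stopf("`times` must be strictly increasing")
    if (max(abs(dt - 1000 / sample_rate)) > 1e-6)
      stopf("`times` spacing must equal 1000/sample_rate = %g ms",
            1000 / sample_rate)
  }
  trials <- as.data.frame(trials)
  need <- c("condition", "response_hand", "rt_ms", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("`trials` lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(trials) != dim(data)[1])
    stopf("annotation rows (%d) != trial count (%d)", nrow(trials), dim(data)[1])
  bad <- setdiff(unique(trials$condition), c("conflict", "nonconflict"))
  if (length(bad)) stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  structure(list(subject_id = subject_id, task_id = task_id,
                 sample_rate = as.numeric(sample_rate), times = as.numeric(times),
                 channels = as.character(channels), data = data,
                 trials = trials),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> subject %s, task %s: %d trials x %d channels x %d samples @ %g Hz [%g, %g] ms\n",
    x$subject_id, x$task_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$sample_rate, min(x$times), max(x$times)))
  print(table(x$trials$condition))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Number of trials per condition
#' @param x an `epoch_set`.
#' @export
condition_counts <- function(x) table(factor(x$trials$condition,
                                             c("conflict", "nonconflict")))

# container I/O -------------------------------------------------------------
# One array store per subject x task: `<stem>.dat` holds, as little-endian
# IEEE doubles, the data tensor (column-major trials x channels x times),
# then the times vector, then rt_ms (NA preserved); `<stem>.json` is the
# metadata sidecar. Doubles are written raw, so the round trip is bit-exact.

#' Write / read the epoch container
#'
#' @param x an `epoch_set`.
#' @param stem path prefix; `<stem>.dat` and `<stem>.json` are created.
#' @return `write_epochs` returns `stem` invisibly; `read_epochs` the
#'   reconstructed `epoch_set`, bit-identical to what was written.
#' @export
write_epochs <- function(x, stem) {
  stopifnot(inherits(x, "epoch_set"))
  dims <- dim(x$data)
  meta <- list(
    container = "conflictMVPA-epochs-v1",
    subject_id = x$subject_id, task_id = x$task_id,
    sample_rate = x$sample_rate, dims = dims, channels = x$channels,
    condition = x$trials$condition,
    response_hand = x$trials$response_hand,
    correct = x$trials$correct)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x$data), con, size = 8, endian = "little")
  writeBin(as.numeric(x$times), con, size = 8, endian = "little")
  writeBin(as.numeric(x$trials$rt_ms), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$container, "conflictMVPA-epochs-v1"))
    stopf("%s.json is not an epoch container sidecar", stem)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  dat <- readBin(con, "double", n, size = 8, endian = "little")
  times <- readBin(con, "double", dims[3], size = 8, endian = "little")
  rt <- readBin(con, "double", dims[1], size = 8, endian = "little")
  epoch_set(array(dat, dims), times, as.numeric(meta$sample_rate), meta$channels,
            data.frame(condition = meta$condition,
                       response_hand = meta$response_hand,
                       rt_ms = rt, correct = meta$correct,
                       stringsAsFactors = FALSE),
            subject_id = meta$subject_id, task_id = meta$task_id)
}

# trial tables --------------------------------------------------------------

#' Write / read a delimited trial table
#'
#' Tab-separated with header `subject task trial condition response_hand
#' rt_ms correct`; missing RTs are written as `NA`.
#' @param tab data.frame of trials.
#' @param path file path.
#' @export
write_trial_table <- function(tab, path) {
  need <- c("subject", "task", "trial", "condition", "response_hand",
            "rt_ms", "correct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("trial table lacks column(s): %s", paste(miss, collapse = ", "))
  utils::write.table(tab[, need], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# EEGLAB import -------------------------------------------------------------

#' Import an EEGLAB .set epoch file
#'
#' Reads the MATLAB v5 file underlying an EEGLAB `.set` dataset (including
#' zlib-compressed v7 variables and a companion `.fdt` float file when the
#' data are stored externally) and maps it onto an [epoch_set]. EEGLAB
#' stores `data` as channels x timepoints x trials in single precision;
#' it is permuted to this package's trials x channels x timepoints order.
#'
#' Condition labels are taken, in order of preference, from a supplied
#' `trials` data.frame, or from the first event type of each epoch in
#' `EEG.epoch` when those types are `"conflict"`/`"nonconflict"`;
#' otherwise annotations default to unknown-free placeholders and should be
#' supplied by the caller.
#'
#' @param path path to the `.set` file.
#' @param trials optional data.frame of annotations (see [epoch_set]).
#' @param subject_id,task_id identifiers; default to the file name.
#' @export
read_eeglab_set <- function(path, trials = NULL, subject_id = NULL,
                            task_id = "task") {
  vars <- read_mat5(path)
  eeg <- if (!is.null(vars$EEG)) vars$EEG else vars
  if (is.list(eeg) && is.null(eeg$data) && length(eeg) == 1L) eeg <- eeg[[1]]
  if (is.null(eeg$data) || is.null(eeg$srate))
    stopf("%s does not look like an EEGLAB dataset (no data/srate)", path)
  dat <- eeg$data
  if (is.character(dat)) {  # external .fdt float file
    fdt <- file.path(dirname(path), basename(dat))
    nch <- as.integer(eeg$nbchan)
    npt <- as.integer(eeg$pnts)
    ntr <- max(1L, as.integer(eeg$trials))
    con <- file(fdt, "rb")
    on.exit(close(con))
    raw <- readBin(con, "double", nch * npt * ntr, size = 4, endian = "little")
    dat <- array(raw, c(nch, npt, ntr))
  }
  if (length(dim(dat)) == 2L) dat <- array(dat, c(dim(dat), 1L))
  dat <- aperm(dat, c(3L, 1L, 2L))  # -> trials x channels x times
  labels <- if (!is.null(eeg$chanlocs)) {
    vapply(eeg$chanlocs, function(cl) as.character(cl$labels), character(1))
  } else paste0("ch", seq_len(dim(dat)[2]))
  n_tr <- dim(dat)[1]
  if (is.null(trials)) {
    cond <- rep("nonconflict", n_tr)
    if (!is.null(eeg$epoch)) {
      types <- vapply(eeg$epoch, function(ep) {
        tt <- ep$eventtype
        if (is.list(tt)) tt <- tt[[1]]
        as.character(tt)[1]
      }, character(1))
      if (all(types %in% c("conflict", "nonconflict"))) cond <- types
    }
    trials <- data.frame(condition = cond, response_hand = "none",
                         rt_ms = NA_real_, correct = 1L,
                         stringsAsFactors = FALSE)
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.set$", "", basename(path))
  epoch_set(dat, as.numeric(eeg$times), as.numeric(eeg$srate), labels,
            trials, subject_id = subject_id, task_id = task_id)
}

# minimal MATLAB v5 reader --------------------------------------------------
# Supports the element types EEGLAB writes: numeric arrays (int8..double,
# single), char, cell and struct arrays, and zlib-compressed (v7) elements.
# Little-endian files only (the only byte order MATLAB and scipy emit on
# the platforms in use).

MI_TYPESIZE <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 4, `6` = 4,
                 `7` = 4, `9` = 8, `12` = 8, `13` = 8, `16` = 1, `17` = 2)

read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128L) stopf("%s: too short to be a MAT-file", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stopf("%s: only little-endian MAT-files are supported", path)
  out <- list()
  pos <- 129L
  while (pos + 8L <= length(raw) + 1L) {
    el <- mat5_element(raw, pos)
    if (is.null(el)) break
    if (!is.null(el$name) && nzchar(el$name)) out[[el$name]] <- el$value
    pos <- el$next_pos
  }
  out
}

mat5_u32 <- function(raw, at)
  readBin(raw[at:(at + 3L)], "integer", 1L, size = 4, endian = "little")

# Parse one top-level element (handles miCOMPRESSED by recursing on the
# inflated bytes). Returns list(name, value, next_pos).
mat5_element <- function(raw, pos) {
  if (pos + 7L > length(raw)) return(NULL)
  type <- mat5_u32(raw, pos)
  small <- bitwAnd(bitwShiftR(type, 16L), 0xFFFFL)
  if (small != 0L) stopf("unexpected small element at top level")
  nbytes <- mat5_u32(raw, pos + 4L)
  body <- raw[(pos + 8L):(pos + 7L + nbytes)]
  next_pos <- pos + 8L + nbytes
  next_pos <- next_pos + (-nbytes) %% 8L
  if (type == 15L) {  # miCOMPRESSED
    body <- memDecompress(body, type = "gzip")
    type <- mat5_u32(body, 1L)
    nb <- mat5_u32(body, 5L)
    body <- body[9:(8L + nb)]
  }
  if (type != 14L) return(list(name = NULL, value = NULL, next_pos = next_pos))
  parsed <- mat5_matrix(body)
  list(name = parsed$name, value = parsed$value, next_pos = next_pos)
}

# Parse subelements of a miMATRIX body into (tag, data) pieces.
mat5_subelements <- function(body) {
  pos <- 1L
  parts <- list()
  while (pos + 3L <= length(body)) {
    first <- mat5_u32(body, pos)
    small_len <- bitwAnd(bitwShiftR(first, 16L), 0xFFFFL)
    if (small_len != 0L) {
      type <- bitwAnd(first, 0xFFFFL)
      data <- body[(pos + 4L):(pos + 3L + small_len)]
      pos <- pos + 8L
    } else {
      type <- first
      nb <- mat5_u32(body, pos + 4L)
      data <- if (nb > 0L) body[(pos + 8L):(pos + 7L + nb)] else raw(0)
      pos <- pos + 8L + nb + (-nb) %% 8L
    }
    parts[[length(parts) + 1L]] <- list(type = type, data = data)
  }
  parts
}

mat5_numeric <- function(part) {
  type <- part$type
  data <- part$data
  sz <- MI_TYPESIZE[[as.character(type)]]
  n <- length(data) %/% sz
  switch(as.character(type),
    `1` = readBin(data, "integer", n, size = 1, signed = TRUE),
    `2` = readBin(data, "integer", n, size = 1, signed = FALSE),
    `3` = readBin(data, "integer", n, size = 2, signed = TRUE, endian = "little"),
    `4` = readBin(data, "integer", n, size = 2, signed = FALSE, endian = "little"),
    `5` = readBin(data, "integer", n, size = 4, endian = "little"),
    `6` = {x <- readBin(data, "integer", n, size = 4, endian = "little")
           ifelse(x < 0, x + 2^32, x)},
    `7` = readBin(data, "double", n, size = 4, endian = "little"),
    `9` = readBin(data, "double", n, size = 8, endian = "little"),
    `16` = data,
    stopf("unsupported MAT data type %d", type))
}

mat5_matrix <- function(body) {
  parts <- mat5_subelements(body)
  flags <- readBin(parts[[1]]$data[1:4], "integer", 1L, size = 4, endian = "little")
  class_id <- bitwAnd(flags, 0xFFL)
  dims <- readBin(parts[[2]]$data, "integer",
                  length(parts[[2]]$data) %/% 4L, size = 4, endian = "little")
  name <- rawToChar(parts[[3]]$data)
  value <- NULL
  if (class_id %in% c(6L, 7L, 8L:15L)) {        # numeric classes
    vals <- mat5_numeric(parts[[4]])
    value <- if (length(dims) > 2L || prod(dims) != length(vals))
      array(as.numeric(vals), dims) else array(as.numeric(vals), dims)
    if (length(dims) == 2L && 1L %in% dims) value <- as.numeric(vals)
  } else if (class_id == 4L) {                  # char
    p <- parts[[4]]
    value <- if (p$type == 16L) rawToChar(p$data) else {
      ints <- mat5_numeric(p)
      intToUtf8(ints[ints > 0])
    }
  } else if (class_id == 1L) {                  # cell
    cells <- lapply(parts[-(1:3)], function(p) mat5_matrix(p$data)$value)
    value <- cells
  } else if (class_id == 2L) {                  # struct (possibly array)
    flen <- readBin(parts[[4]]$data, "integer", 1L, size = 4, endian = "little")
    fnames_raw <- parts[[5]]$data
    nf <- length(fnames_raw) %/% flen
    fnames <- vapply(seq_len(nf), function(i) {
      chunk <- fnames_raw[((i - 1L) * flen + 1L):(i * flen)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, character(1))
    fields <- lapply(parts[-(1:5)], function(p) mat5_matrix(p$data)$value)
    n_elem <- prod(dims)
    elems <- lapply(seq_len(n_elem), function(e) {
      el <- fields[((e - 1L) * nf + 1L):(e * nf)]
      names(el) <- fnames
      el
    })
    value <- if (n_elem == 1L) elems[[1]] else elems
  } else {
    stopf("unsupported MAT array class %d", class_id)
  }
  list(name = name, value = value)
}
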