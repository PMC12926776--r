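#' Electrode montage
#'
#' A montage holds the ordered channel labels, 2-D schematic scalp positions
#' (x = left-to-right, y = back-to-front, unit head radius) and a symmetric
#' channel neighbor graph used by graph-based TFCE neighborhoods and by the
#' synthetic generator's spatial effect templates.
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix (channels x 2) of layout coordinates.
#' @param neighbor_dist distance threshold for connecting channels. The
#'   default, 1.4 times the median nearest-neighbor distance, yields a
#'   connected graph of immediate spatial neighbors on the shipped layout.
#' @return an object of class `eeg_montage`: list with `labels`, `positions`
#'   and logical adjacency matrix `adjacency` (symmetric, no self-edges).
#' @export
montage <- function(labels, positions, neighbor_dist = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stopf("montage labels must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 2L)
    stopf("`positions` must be a %d x 2 matrix", length(labels))
  rownames(positions) <- labels
  d <- as.matrix(stats::dist(positions))
  if (is.null(neighbor_dist)) {
    nn <- apply(d + diag(Inf, nrow(d)), 1, min)
    neighbor_dist <- 1.4 * stats::median(nn)
  }
  adj <- d > 0 & d <= neighbor_dist
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  dimnames(adj) <- list(labels, labels)
  structure(list(labels = labels, positions = positions, adjacency = adj),
            class = "eeg_montage")
}

#' Default 28-channel montage
#'
#' The intersection-scale cap used throughout the package: 28 canonical
#' 10-20/10-10 labels with schematic 2-D positions, shipped as a plain-text
#' fixture. Represents the common electrode set one obtains after
#' harmonizing a 64-channel and a 32-channel recording system.
#'
#' @inheritParams montage
#' @export
default_montage <- function(neighbor_dist = NULL) {
  path <- system.file("extdata", "montage28.csv", package = "conflictMVPA",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  montage(tab$label, cbind(tab$x, tab$y), neighbor_dist = neighbor_dist)
}

#' Restrict a montage to a channel subset
#'
#' @param m an `eeg_montage`.
#' @param channels labels to keep; order taken from the montage (canonical
#'   order), not from `channels`.
#' @export
subset_montage <- function(m, channels) {
  keep <- m$labels[m$labels %in% channels]
  if (!length(keep)) stopf("no requested channel present in montage")
  idx <- match(keep, m$labels)
  structure(list(labels = keep,
                 positions = m$positions[idx, , drop = FALSE],
                 adjacency = m$adjacency[idx, idx, drop = FALSE]),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels, %d neighbor edges\n",
              length(x$labels), sum(x$adjacency) / 2))
  invisible(x)
}

#' Fronto-central spatial template
#'
#' Unit-norm channel weight vector concentrated over fronto-central sensors
#' (Gaussian in layout distance from a point midway between Fz and Cz),
#' where conflict-related activity such as the N2 and midfrontal theta is
#' classically maximal. Used as the default shared conflict pattern of the
#' synthetic generator.
#'
#' @param m an `eeg_montage`.
#' @param center 2-D layout coordinates of the template peak.
#' @param width Gaussian width in layout units.
#' @export
frontocentral_template <- function(m, center = c(0, 0.25), width = 0.35) {
  d2 <- rowSums(sweep(m$positions, 2, center)^2)
  unit_norm(exp(-d2 / (2 * width^2)))
}
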