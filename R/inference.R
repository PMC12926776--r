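#' Grid neighborhoods for cluster statistics
#'
#' TFCE and the cluster permutation test operate on arbitrary symmetric
#' neighborhoods represented as an edge list. These helpers build the three
#' kinds used by the package's maps.
#'
#' @param n number of cells in a 1-D (time) grid.
#' @return a 2-column integer matrix of undirected edges (1-based cell
#'   indices).
#' @export
chain_edges <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  cbind(seq_len(n - 1L), 2:n)
}

#' @rdname chain_edges
#' @param dims `c(nrow, ncol)` of a 2-D lattice (4-connectivity,
#'   column-major cell indexing as produced by flattening a matrix).
#' @export
lattice_edges <- function(dims) {
  nr <- dims[1]; nc <- dims[2]
  idx <- matrix(seq_len(nr * nc), nr, nc)
  rbind(cbind(as.vector(idx[-nr, , drop = FALSE]),
              as.vector(idx[-1, , drop = FALSE])),
        cbind(as.vector(idx[, -nc, drop = FALSE]),
              as.vector(idx[, -1, drop = FALSE])))
}

#' @rdname chain_edges
#' @param adjacency symmetric logical channel adjacency (e.g. from an
#'   [eeg_montage][montage]).
#' @param n_steps number of time (or frequency) steps; cells are indexed
#'   channel-fastest, matching flattened channel x step maps. Neighbors are
#'   adjacent channels at the same step plus the same channel at adjacent
#'   steps.
#' @export
graph_time_edges <- function(adjacency, n_steps) {
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stopf("channel adjacency must be symmetric")
  nch <- nrow(adjacency)
  ut <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  spatial <- do.call(rbind, lapply(seq_len(n_steps), function(s)
    cbind(ut[, 1] + (s - 1L) * nch, ut[, 2] + (s - 1L) * nch)))
  temporal <- if (n_steps > 1) {
    base <- seq_len(nch)
    do.call(rbind, lapply(seq_len(n_steps - 1L), function(s)
      cbind(base + (s - 1L) * nch, base + s * nch)))
  } else matrix(integer(0), 0, 2)
  rbind(spatial, temporal)
}

resolve_edges <- function(values, neighborhood) {
  if (is.null(neighborhood)) {
    if (is.matrix(values)) return(lattice_edges(dim(values)))
    return(chain_edges(length(values)))
  }
  is_square_adj <- is.matrix(neighborhood) &&
    nrow(neighborhood) == ncol(neighborhood) &&
    nrow(neighborhood) == length(values)
  if (!is_square_adj && is.matrix(neighborhood) && ncol(neighborhood) == 2L &&
      !is.logical(neighborhood))
    return(neighborhood)
  if (is_square_adj) {
    if (!isTRUE(all.equal(neighborhood, t(neighborhood))))
      stopf("adjacency matrix must be symmetric")
    if (any(diag(neighborhood) != 0)) stopf("adjacency must have no self-edges")
    ut <- which(neighborhood & upper.tri(neighborhood), arr.ind = TRUE)
    return(unname(ut))
  }
  stopf("cannot interpret `neighborhood`")
}

#' Threshold-free cluster enhancement
#'
#' Enhances each map cell by `sum_h extent(cell, h)^E * h^H * dh` over
#' thresholds `h = dh, 2dh, ...` up to the map maximum, where `extent` is
#' the size of the supra-threshold cluster containing the cell at height
#' `h`. Supports 1-D chains, 2-D lattices and arbitrary graph
#' neighborhoods. With `tails = "two"` the same transform is applied to the
#' negated map and subtracted, so negative effects receive negative
#' enhancement.
#'
#' @param values numeric vector or matrix (finite).
#' @param neighborhood `NULL` (chain for vectors, 4-connected lattice for
#'   matrices), an edge list (2-column matrix) or a symmetric adjacency
#'   matrix.
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh threshold step in the map's units (default 0.1).
#' @param tails `"one"` (positive tail only) or `"two"`.
#' @return enhanced map with the same shape as `values`.
#' @export
tfce <- function(values, neighborhood = NULL, E = 0.5, H = 2, dh = 0.1,
                 tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (!all(is.finite(values))) stopf("map values must be finite")
  check_scalar_number(E, "E", lower = 1e-12)
  check_scalar_number(H, "H", lower = 1e-12)
  check_scalar_number(dh, "dh", lower = 1e-12)
  edges <- resolve_edges(values, neighborhood)
  v <- as.numeric(values)
  enh <- tfce_cpp(v, edges[, 1], edges[, 2], E, H, dh)
  if (tails == "two")
    enh <- enh - tfce_cpp(-v, edges[, 1], edges[, 2], E, H, dh)
  if (is.matrix(values)) enh <- matrix(enh, nrow(values), ncol(values))
  enh
}

# union-find components of a logical mask restricted to an edge list
mask_components <- function(mask, edges) {
  n <- length(mask)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    keep <- mask[edges[, 1]] & mask[edges[, 2]]
    for (e in which(keep)) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[b] <- a
    }
  }
  comp <- rep(NA_integer_, n)
  roots <- vapply(which(mask), find, 0L)
  comp[mask] <- match(roots, unique(roots))
  comp
}

#' Group-level TFCE cluster permutation test
#'
#' Centers each subject's accuracy map at chance, computes the one-sample
#' t-map across subjects, enhances it with [tfce], and compares it to a
#' max-statistic null built from `n_iter` random whole-map sign flips of
#' the subject maps. The corrected p of a cell is the proportion of null
#' maxima at least as large as its observed enhanced value; cells with
#' p < `alpha` form the significant mask, whose connected components are
#' reported as clusters with their grid extents. Zero-variance cells take a
#' large finite sentinel t (sign of the mean) so degenerate maps rank above
#' any finite-variance null rather than propagating NaN.
#'
#' @param subject_maps list of single-subject [decoding_map]s on identical
#'   grids, or a subjects x cells numeric matrix.
#' @param neighborhood as in [tfce]; default inferred from the map grid
#'   (chain / lattice).
#' @param chance value subtracted from every map (0.5 for balanced
#'   two-class decoding).
#' @param E,H,dh TFCE parameters; `dh` is in t units.
#' @param n_iter Monte-Carlo sign-flip iterations (default 10000).
#' @param tails `"one"` tests above-chance decoding only (directional
#'   hypotheses, the default); `"two"` uses |t|.
#' @param alpha family-wise error level for the significant mask.
#' @param statistic `"t"` (default) or `"mean"` (cluster statistic computed
#'   on the chance-centered group mean map; `dh` is then in accuracy units).
#' @param seed RNG seed for the sign flips.
#' @param axes optional named list of axis coordinates for cluster
#'   reporting (taken from the maps when available).
#' @return object of class `cluster_inference`: `t_map`, `tfce_map`,
#'   `p` (corrected), `mask`, `clusters` (data.frame), `null_max`, params.
#' @export
montecarlo_cluster_stat <- function(subject_maps, neighborhood = NULL,
                                    chance = 0.5, E = 0.5, H = 2, dh = 0.1,
                                    n_iter = 10000, tails = c("one", "two"),
                                    alpha = 0.05, statistic = c("t", "mean"),
                                    seed = 1L, axes = NULL) {
  tails <- match.arg(tails)
  statistic <- match.arg(statistic)
  st <- stack_maps(subject_maps)
  if (is.null(axes)) axes <- st$axes
  M <- st$values - chance
  ns <- nrow(M)
  if (ns < 2) stopf("need at least 2 subjects")
  shape <- if (!is.null(axes)) vapply(axes, length, 0L) else ncol(M)
  grid_values <- if (length(shape) == 2L) matrix(0, shape[1], shape[2]) else
    numeric(ncol(M))
  edges <- resolve_edges(grid_values, neighborhood)

  mu <- colMeans(M)
  sentinel <- 100
  if (statistic == "t") {
    sdv <- apply(M, 2, stats::sd)
    tmap <- ifelse(sdv > 0, mu / (sdv / sqrt(ns)),
                   sign(mu) * sentinel)
    # |t| capped at the sentinel so near-degenerate cells keep the TFCE
    # threshold ladder (dh in t units) finite; the cap is far beyond any
    # interpretable t and never affects ranking among ordinary cells
    tmap <- pmin(pmax(tmap, -sentinel), sentinel)
  } else {
    tmap <- mu
  }
  stat_obs <- if (tails == "two") abs(tmap) else tmap
  enh <- tfce_cpp(stat_obs, edges[, 1], edges[, 2], E, H, dh)
  null_max <- with_seed(derive_seed(seed, "signflip"), {
    tfce_maxnull_cpp(M, edges[, 1], edges[, 2], E, H, dh, n_iter,
                     sentinel, tails == "two", statistic == "mean")
  })
  p <- vapply(enh, function(e) mean(null_max >= e), 0.0)
  mask <- p < alpha & enh > 0
  comp <- mask_components(mask, edges)
  clusters <- cluster_table(comp, tmap, p, axes, shape)
  structure(list(
    t_map = if (length(shape) == 2L) matrix(tmap, shape[1], shape[2]) else tmap,
    tfce_map = if (length(shape) == 2L) matrix(enh, shape[1], shape[2]) else enh,
    p = if (length(shape) == 2L) matrix(p, shape[1], shape[2]) else p,
    mask = if (length(shape) == 2L) matrix(mask, shape[1], shape[2]) else mask,
    clusters = clusters, null_max = null_max, axes = axes,
    params = list(chance = chance, E = E, H = H, dh = dh, n_iter = n_iter,
                  tails = tails, alpha = alpha, statistic = statistic,
                  seed = seed, n_subjects = ns)),
    class = "cluster_inference")
}

cluster_table <- function(comp, stat, p, axes, shape) {
  ids <- sort(unique(comp[!is.na(comp)]))
  if (!length(ids))
    return(data.frame(cluster = integer(0), n_cells = integer(0),
                      peak_stat = numeric(0), min_p = numeric(0)))
  rows <- lapply(ids, function(id) {
    cells <- which(!is.na(comp) & comp == id)
    row <- data.frame(cluster = id, n_cells = length(cells),
                      peak_stat = max(stat[cells]), min_p = min(p[cells]))
    if (!is.null(axes)) {
      if (length(shape) == 1L) {
        ax <- axes[[1]]
        row[[paste0(names(axes)[1], "_start")]] <- min(ax[cells])
        row[[paste0(names(axes)[1], "_end")]] <- max(ax[cells])
      } else {
        rc <- arrayInd(cells, shape)
        for (d in seq_along(axes)) {
          ax <- axes[[d]]
          row[[paste0(names(axes)[d], "_start")]] <- min(ax[rc[, d]])
          row[[paste0(names(axes)[d], "_end")]] <- max(ax[rc[, d]])
        }
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' @export
print.cluster_inference <- function(x, ...) {
  cat(sprintf("<cluster_inference> %d subjects, %d cells, %d significant (alpha %.2f, %s-tailed)\n",
              x$params$n_subjects, length(x$p), sum(x$mask),
              x$params$alpha, x$params$tails))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Stack single-subject decoding maps into a group matrix
#'
#' @param maps list of [decoding_map]s on identical grids, or an already
#'   stacked subjects x cells matrix.
#' @return list with `values` (subjects x cells) and `axes`.
#' @export
stack_maps <- function(maps) {
  if (is.matrix(maps) && !inherits(maps, "decoding_map"))
    return(list(values = maps, axes = NULL))
  stopifnot(is.list(maps), length(maps) >= 1)
  ax <- maps[[1]]$axes
  for (m in maps[-1])
    if (!isTRUE(all.equal(m$axes, ax)))
      stopf("maps are not on identical grids")
  vals <- do.call(rbind, lapply(maps, function(m) as.numeric(m$values)))
  list(values = vals, axes = ax)
}

#' Resampled group-level null for decoding accuracy
#'
#' Builds the group null of the mean decoding accuracy from per-subject
#' label-permutation accuracies: each of `n_draws` draws picks one permuted
#' accuracy per subject uniformly at random and averages across subjects.
#' The observed group mean is located in this distribution as a midrank
#' percentile, `100 * (#draws < observed + 0.5 * #draws == observed) /
#' n_draws`; values above the `threshold` percentile (default 95) indicate
#' above-chance decoding, values below it evidence for the null.
#'
#' @param observed observed group-mean accuracy.
#' @param per_subject_perms subjects x n_perm matrix of label-permuted
#'   accuracies (n_perm >= 2, typically 100).
#' @param n_draws resampling draws (default 10000).
#' @param threshold significance percentile.
#' @param seed RNG seed.
#' @return object of class `permutation_null`.
#' @export
stelzer_null <- function(observed, per_subject_perms, n_draws = 10000,
                         threshold = 95, seed = 1L) {
  P <- as.matrix(per_subject_perms)
  if (ncol(P) < 2) stopf("need at least 2 permutations per subject")
  ns <- nrow(P)
  draws <- with_seed(derive_seed(seed, "stelzer"), {
    picks <- matrix(sample.int(ncol(P), ns * n_draws, replace = TRUE),
                    ns, n_draws)
    colMeans(matrix(P[cbind(rep(seq_len(ns), n_draws), as.vector(picks))],
                    ns, n_draws))
  })
  percentile <- 100 * (sum(draws < observed) + 0.5 * sum(draws == observed)) /
    n_draws
  structure(list(observed = observed, group_draws = draws,
                 percentile = percentile, threshold = threshold,
                 significant = percentile > threshold,
                 n_draws = n_draws, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> observed %.4f at percentile %.1f of %d draws (threshold %g) -> %s\n",
              x$observed, x$percentile, x$n_draws, x$threshold,
              if (x$significant) "above-chance" else "consistent with chance"))
  invisible(x)
}

#' Per-subject label-permutation accuracies (frequency-domain decoding)
#'
#' Recomputes the frequency-domain decoding accuracy `n_perm` times with
#' condition labels randomly permuted within the subject, feeding
#' [stelzer_null]. Spectral features are computed once; each permutation
#' redraws a balanced partition on the permuted labels.
#'
#' @inheritParams decode_frequency
#' @param n_perm number of permutations (default 100).
#' @return numeric vector of length `n_perm`.
#' @export
permuted_accuracies <- function(epochs, fconfig = frequency_config(),
                                n_perm = 100, lambda = 0.01, k = 10,
                                seed = 1L, label = "condition") {
  sel <- select_label(epochs, label)
  X <- unclass(fft_power_features(sel$epochs, fconfig))
  classes <- sort(unique(sel$y))
  vapply(seq_len(n_perm), function(i) {
    yp <- with_seed(derive_seed(seed, "labelperm", i), sample(sel$y))
    part <- balanced_partition(yp, k, 1, derive_seed(seed, "permpart", i))
    cv_accuracy_cpp(X, label01(yp, classes), part$repeats, lambda,
                    fconfig$z_transform == "foldwise")
  }, 0.0)
}

# JZS Bayes factors ----------------------------------------------------------

#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Default Bayesian t-test with a Cauchy(0, r) prior on the standardized
#' effect size (Jeffreys-Zellner-Siow form: effect | g ~ N(0, g), g scaled
#' inverse-chi-square). The Bayes factor in favor of an effect is
#' \deqn{BF_{10} = \int_0^\infty (1+ng)^{-1/2}
#'   \left(\frac{1 + t^2/((1+ng)\nu)}{1 + t^2/\nu}\right)^{-(\nu+1)/2}
#'   \pi(g)\, dg, \quad \nu = n - 1,}
#' evaluated by adaptive quadrature (the ratio form keeps the integrand
#' well-scaled even for |t| large enough that BF10 reaches 1e100 and
#' beyond). BF10 depends on t only through t^2, so the sign of t is
#' irrelevant. BF01 = 1 / BF10.
#'
#' @param t observed t statistic (ignored when `x` is given).
#' @param n sample size (pairs for a paired test); df = n - 1.
#' @param x optional data vector; the one-sample t against `mu` is computed
#'   internally.
#' @param mu null value used with `x`.
#' @param r Cauchy prior scale (default sqrt(2)/2).
#' @param rel_tol quadrature relative tolerance.
#' @return BF10 (> 0).
#' @export
bf10_ttest <- function(t = NULL, n = NULL, x = NULL, mu = 0,
                       r = sqrt(2) / 2, rel_tol = 1e-8) {
  if (!is.null(x)) {
    n <- length(x)
    if (n < 2) stopf("need n >= 2")
    s <- stats::sd(x)
    if (s == 0) stopf("zero variance: t statistic undefined")
    t <- (mean(x) - mu) / (s / sqrt(n))
  }
  if (is.null(t) || is.null(n)) stopf("provide either (t, n) or x")
  if (!is.finite(t)) stopf("t must be finite")
  if (n < 2) stopf("need n >= 2")
  nu <- n - 1
  t2 <- t^2
  log_ratio <- function(g)
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * (log1p(t2 / ((1 + n * g) * nu)) - log1p(t2 / nu))
  # prior density of g: scaled inverse-chi-square equivalent to Cauchy(0, r)
  log_prior <- function(g)
    0.5 * log(r^2 / (2 * pi)) - 1.5 * log(g) - r^2 / (2 * g)
  res <- tryCatch(
    stats::integrate(function(g) exp(log_ratio(g) + log_prior(g)),
                     0, Inf, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) stopf("quadrature failed: %s", conditionMessage(e)))
  if (res$message != "OK" ||
      (res$value > 0 && res$abs.error / res$value > 100 * rel_tol))
    stopf("quadrature did not converge (value %g, abs.error %g, message '%s')",
          res$value, res$abs.error, res$message)
  res$value
}

#' Evidence band of a Bayes factor
#'
#' Interpretation thresholds: below 1/3 substantial evidence for the null,
#' 1/3-3 inconclusive, 3-20 substantial, 20-150 strong, above 150 very
#' strong evidence for the effect.
#'
#' @param bf10 numeric vector of BF10 values.
#' @export
bf_band <- function(bf10) {
  cut(bf10, c(-Inf, 1 / 3, 3, 20, 150, Inf),
      labels = c("supports_null", "inconclusive", "substantial", "strong",
                 "very_strong"),
      right = TRUE)
}

# column-wise JZS BF against zero with zero-variance handling: identical
# values at the null give t = 0 (null-favoring); identical nonzero values
# have a divergent t, represented by a large finite sentinel
bf10_map <- function(M, r = sqrt(2) / 2) {
  n <- nrow(M)
  apply(M, 2, function(col) {
    if (stats::sd(col) == 0) {
      t_eff <- if (mean(col) == 0) 0 else sign(mean(col)) * 100
      bf10_ttest(t = t_eff, n = n, r = r)
    } else bf10_ttest(x = col, r = r)
  })
}

#' Per-cell Bayes factors for group decoding maps
#'
#' One-sample JZS Bayes factor against chance at every grid cell, with the
#' evidence band at the 1/3 and 3 thresholds (plus 20/150 annotations).
#'
#' @param subject_maps list of [decoding_map]s or subjects x cells matrix.
#' @param chance null accuracy (0.5).
#' @param r Cauchy prior scale.
#' @return data.frame with `cell`, axis coordinates when available, `bf10`
#'   and `band`.
#' @export
bf_timecourse <- function(subject_maps, chance = 0.5, r = sqrt(2) / 2) {
  st <- stack_maps(subject_maps)
  bf <- bf10_map(st$values - chance, r)
  out <- data.frame(cell = seq_along(bf), bf10 = bf, band = bf_band(bf))
  if (!is.null(st$axes) && length(st$axes) == 1L)
    out[[names(st$axes)[1]]] <- st$axes[[1]]
  out
}

#' Paired condition comparison with effect size and Bayes factor
#'
#' Paired t-test, two-sided p, the paired-design effect size
#' `d_av = |M1 - M2| / ((SD1 + SD2) / 2)`, the 95% CI of the mean
#' difference, and the JZS BF10 computed from the observed t.
#'
#' @param x,y condition vectors (equal length when paired).
#' @param paired paired design (default).
#' @param r Cauchy prior scale for the Bayes factor.
#' @return object of class `effect_summary` (also a one-row data.frame)
#'   with columns `n`, `mean_diff`, `t`, `df`, `p`, `d_av`, `ci_lo`,
#'   `ci_hi`, `bf10`, `bf01`.
#' @export
effect_summary <- function(x, y, paired = TRUE, r = sqrt(2) / 2) {
  if (paired && length(x) != length(y))
    stopf("paired comparison requires equal lengths")
  if (paired && stats::sd(x - y) == 0)
    stopf("zero variance of paired differences: t statistic undefined")
  tt <- stats::t.test(x, y, paired = paired)
  n <- if (paired) length(x) else length(x) + length(y)
  bf <- if (paired) bf10_ttest(t = unname(tt$statistic), n = length(x), r = r)
        else NA_real_
  out <- data.frame(n = n, mean_diff = unname(tt$estimate[1]),
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value,
                    d_av = d_av(mean(x), stats::sd(x), mean(y), stats::sd(y)),
                    ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                    bf10 = bf, bf01 = 1 / bf)
  class(out) <- c("effect_summary", class(out))
  out
}

#' Paired-design effect size from summary statistics
#'
#' `d_av = |M1 - M2| / ((SD1 + SD2) / 2)`: the mean difference scaled by
#' the average of the two condition SDs.
#'
#' @param m1,s1 mean and SD of condition 1.
#' @param m2,s2 mean and SD of condition 2.
#' @export
d_av <- function(m1, s1, m2, s2) abs(m1 - m2) / ((s1 + s2) / 2)
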