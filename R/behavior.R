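#' Per-condition behavioral summaries
#'
#' Subject-level means are computed first (accuracy over all screened
#' trials; RT over screened trials with a response), then group statistics
#' are taken over subject means — the standard repeated-measures
#' aggregation, whose group SDs are between-subject SDs.
#'
#' @param tab trial table (`subject`, `task`, `condition`, `rt_ms`,
#'   `correct`), already screened or screenable via `rules`.
#' @param rules optional [screening_rules] applied first.
#' @return list with `subject` (per subject x task x condition means) and
#'   `group` (mean/SD of subject means plus subject counts).
#' @export
summarize_behavior <- function(tab, rules = NULL) {
  if (!is.null(rules)) tab <- screen_trial_table(tab, rules)$table
  key <- interaction(tab$subject, tab$task, tab$condition, drop = TRUE)
  subject <- do.call(rbind, lapply(split(tab, key), function(d)
    data.frame(subject = d$subject[1], task = d$task[1],
               condition = d$condition[1], n_trials = nrow(d),
               accuracy = mean(d$correct),
               rt_ms = mean(d$rt_ms[!is.na(d$rt_ms)]),
               stringsAsFactors = FALSE)))
  rownames(subject) <- NULL
  dropped <- !is.finite(subject$rt_ms) | subject$n_trials == 0
  if (any(dropped))
    message(sprintf("%d subject x task x condition cell(s) without valid trials excluded",
                    sum(dropped)))
  subject <- subject[!dropped, , drop = FALSE]
  gkey <- interaction(subject$task, subject$condition, drop = TRUE)
  group <- do.call(rbind, lapply(split(subject, gkey), function(d)
    data.frame(task = d$task[1], condition = d$condition[1],
               n_subjects = nrow(d),
               mean_accuracy = mean(d$accuracy), sd_accuracy = stats::sd(d$accuracy),
               mean_rt_ms = mean(d$rt_ms), sd_rt_ms = stats::sd(d$rt_ms),
               stringsAsFactors = FALSE)))
  rownames(group) <- NULL
  list(subject = subject, group = group)
}

#' Per-subject conflict effects
#'
#' Non-conflict minus conflict differences per subject and task, for both
#' accuracy and RT: positive `d_accuracy` is the canonical conflict cost on
#' accuracy; the canonical RT slowing under conflict appears as *negative*
#' `d_rt_ms` under this subtraction order.
#'
#' @param summaries output of [summarize_behavior] (its `subject` element
#'   is used) or an equivalent per-subject data.frame.
#' @return data.frame with one row per subject x task: `d_accuracy`,
#'   `d_rt_ms`.
#' @export
conflict_effects <- function(summaries) {
  subj <- if (is.list(summaries) && !is.data.frame(summaries))
    summaries$subject else summaries
  key <- interaction(subj$subject, subj$task, drop = TRUE)
  out <- do.call(rbind, lapply(split(subj, key), function(d) {
    con <- d[d$condition == "conflict", ]
    non <- d[d$condition == "nonconflict", ]
    if (nrow(con) != 1 || nrow(non) != 1) return(NULL)
    data.frame(subject = d$subject[1], task = d$task[1],
               d_accuracy = non$accuracy - con$accuracy,
               d_rt_ms = non$rt_ms - con$rt_ms,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# midrank Spearman rho with two-sided p (t approximation, or exact
# permutation for small n)
spearman_test <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))           # midranks by default
  if (exact && n <= 10) {
    perms <- combinat_permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    null <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(null) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  c(rho = rho, p = p, n = n)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Cross-task correlations of conflict effects
#'
#' Spearman correlations (midrank ties) of per-subject conflict effects
#' between every task pair, with two-sided p values from the t
#' approximation (exact permutation p for n <= 10 when `exact = TRUE`).
#'
#' @param effects output of [conflict_effects].
#' @param measure `"d_accuracy"` or `"d_rt_ms"`.
#' @param exact use the exact permutation null for small samples.
#' @return list with matrices `rho`, `p`, `n` (task x task); constant
#'   columns yield NA with a warning.
#' @export
cross_task_correlations <- function(effects, measure = c("d_rt_ms", "d_accuracy"),
                                    exact = FALSE) {
  measure <- match.arg(measure)
  wide <- stats::reshape(effects[, c("subject", "task", measure)],
                         idvar = "subject", timevar = "task",
                         direction = "wide")
  tasks <- sub(paste0("^", measure, "\\."), "",
               setdiff(names(wide), "subject"))
  X <- as.matrix(wide[, -1, drop = FALSE])
  colnames(X) <- tasks
  nt <- length(tasks)
  rho <- p <- nmat <- matrix(NA_real_, nt, nt, dimnames = list(tasks, tasks))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) { rho[i, j] <- 1; next }
    ok <- is.finite(X[, i]) & is.finite(X[, j])
    if (sum(ok) < 3) next
    res <- spearman_test(X[, i], X[, j], exact = exact)
    rho[i, j] <- res["rho"]; p[i, j] <- res["p"]; nmat[i, j] <- res["n"]
  }
  if (any(is.na(rho[upper.tri(rho)])))
    warning("some correlations undefined (constant column or too few pairs)",
            call. = FALSE)
  list(rho = rho, p = p, n = nmat, measure = measure)
}
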