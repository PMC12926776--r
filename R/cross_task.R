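#' Cross-task temporal generalization
#'
#' Trains the classifier on *all* class-balanced trials of the training
#' task at each training timepoint and tests it at every timepoint of the
#' other task, yielding a train-time x test-time accuracy matrix. No
#' cross-validation is involved: no trial of the training task is ever
#' scored. Balancing subsamples both tasks to a common per-condition trial
#' count (the minimum across the two tasks and conditions), eliminating
#' class and task imbalance as confounds. Directions A->B and B->A are
#' separate analyses and are never averaged.
#'
#' @param train,test [epoch_set]s of the same subject on harmonized
#'   channels.
#' @param lambda LDA shrinkage.
#' @param seed seed for the balancing subsample.
#' @param label decode the conflict condition (default) or response hand
#'   (the control analysis).
#' @param time_step optional grid spacing (ms) at which to evaluate both
#'   axes; the full sample grid is used when `NULL`. Different tasks keep
#'   their own (possibly different-length) time axes.
#' @param n_per_class override the per-condition trial count.
#' @return a [decoding_map] on the `train_time` x `test_time` grid.
#' @export
cross_task_matrix <- function(train, test, lambda = 0.01, seed = 1L,
                              label = "condition", time_step = NULL,
                              n_per_class = NULL) {
  if (!identical(train$channels, test$channels))
    stopf("channel sets differ; run harmonize_channels() on the epoch sets first")
  bal <- balance_across_tasks(train, test, label, seed, n_per_class)
  tr <- decimate_grid(bal$train, time_step)
  te <- decimate_grid(bal$test, time_step)
  acc <- cross_matrix_cpp(tr$epochs$data, te$epochs$data,
                          bal$ytr01, bal$yte01, lambda)
  decoding_map(acc, list(train_time = tr$times, test_time = te$times),
               list(subject = train$subject_id,
                    train_task = train$task_id, test_task = test$task_id,
                    label_type = label, lambda = lambda, seed = seed,
                    n_per_class = bal$n_per_class))
}

#' Cross-task decoding in the frequency domain
#'
#' Fits the classifier on the training task's full spectral feature matrix
#' and evaluates it on the test task's, with the z-transformation fitted on
#' the training task only.
#'
#' @inheritParams cross_task_matrix
#' @param fconfig a [frequency_config].
#' @return scalar accuracy with attribute `meta`.
#' @export
cross_task_frequency <- function(train, test, fconfig = frequency_config(),
                                 lambda = 0.01, seed = 1L,
                                 label = "condition", n_per_class = NULL) {
  if (!identical(train$channels, test$channels))
    stopf("channel sets differ; run harmonize_channels() on the epoch sets first")
  bal <- balance_across_tasks(train, test, label, seed, n_per_class)
  Xtr <- unclass(fft_power_features(bal$train, fconfig))
  Xte <- unclass(fft_power_features(bal$test, fconfig))
  m <- colMeans(Xtr)
  s <- apply(Xtr, 2, stats::sd)
  zz <- s == 0
  Xtr <- sweep(sweep(Xtr, 2, m), 2, ifelse(zz, 1, s), "/")
  Xte <- sweep(sweep(Xte, 2, m), 2, ifelse(zz, 1, s), "/")
  Xtr[, zz] <- 0
  Xte[, zz] <- 0
  fit <- lda_train_cpp(Xtr, bal$ytr01, lambda)
  pred <- as.numeric(Xte %*% fit$w + fit$b) > 0
  acc <- mean(pred == (bal$yte01 == 1))
  structure(acc, meta = list(subject = train$subject_id,
                             train_task = train$task_id,
                             test_task = test$task_id,
                             label_type = label, lambda = lambda,
                             seed = seed, domain = "frequency"))
}

# subsample both tasks to a common per-class count, without replacement
balance_across_tasks <- function(train, test, label, seed,
                                 n_per_class = NULL) {
  seltr <- select_label(train, label)
  selte <- select_label(test, label)
  classes <- sort(unique(c(seltr$y, selte$y)))
  if (length(classes) != 2L ||
      !all(classes %in% seltr$y) || !all(classes %in% selte$y))
    stopf("both classes must be present in both tasks")
  n <- min(table(factor(seltr$y, classes)), table(factor(selte$y, classes)))
  if (!is.null(n_per_class)) {
    if (n_per_class > n) stopf("n_per_class = %d exceeds available minimum %d",
                               n_per_class, n)
    n <- n_per_class
  }
  sub_one <- function(sel, tag) {
    keep <- with_seed(derive_seed(seed, "balance", tag), {
      sort(unlist(lapply(classes, function(cl)
        sample(which(sel$y == cl), n)), use.names = FALSE))
    })
    out <- sel$epochs
    out$data <- out$data[keep, , , drop = FALSE]
    out$trials <- out$trials[keep, , drop = FALSE]
    list(epochs = out, y = sel$y[keep])
  }
  btr <- sub_one(seltr, paste0("train.", train$task_id))
  bte <- sub_one(selte, paste0("test.", test$task_id))
  list(train = btr$epochs, test = bte$epochs,
       ytr01 = label01(btr$y, classes), yte01 = label01(bte$y, classes),
       n_per_class = n)
}

decimate_grid <- function(epochs, time_step) {
  if (is.null(time_step)) return(list(epochs = epochs, times = epochs$times))
  dt <- 1000 / epochs$sample_rate
  stride <- max(1L, as.integer(round(time_step / dt)))
  keep <- seq(1L, length(epochs$times), by = stride)
  out <- epochs
  out$data <- epochs$data[, , keep, drop = FALSE]
  out$times <- epochs$times[keep]
  out$sample_rate <- epochs$sample_rate / stride
  list(epochs = out, times = out$times)
}
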