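#' Class-balanced cross-validation partition
#'
#' Stratified k-fold assignment in which the majority class is first
#' subsampled without replacement (independently per balancing repeat) to
#' the minority-class count, so that every fold's train and test sets
#' contain equal numbers of both classes. Trials left out by the
#' subsampling are simply unused in that repeat; no trial is ever
#' duplicated within a repeat.
#'
#' @param labels two-class label vector (character/factor); classes are
#'   ordered alphabetically, the first being "class0" for tie-breaking.
#' @param k number of folds (default 10: train on 90%, test on 10%).
#' @param n_repeats balancing repeats; accuracies are averaged across them.
#' @param seed integer seed; identical inputs give identical partitions.
#' @return object of class `fold_partition`: list with `k`, `n_repeats`,
#'   `seed`, `classes` and `repeats`, a list (per repeat) of lists (per
#'   fold) of `train` / `test` index vectors.
#' @export
balanced_partition <- function(labels, k = 10, n_repeats = 1, seed = 1L) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L)
    stopf("need exactly 2 classes, got %d", length(classes))
  idx <- split(seq_along(labels), factor(as.character(labels), classes))
  m <- min(lengths(idx))
  if (m < k)
    stopf("minimum class count (%d) is below k = %d; use a smaller k", m, k)
  sizes <- rep(m %/% k, k) + c(rep(1L, m %% k), rep(0L, k - m %% k))
  fold_of <- rep(seq_len(k), sizes)
  repeats <- lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, "partition", r), {
      sel <- lapply(idx, function(ix) sample(ix, m))   # subsample + shuffle
      assign_fold <- lapply(sel, function(ix) split(ix, fold_of))
      lapply(seq_len(k), function(f) {
        test <- c(assign_fold[[1]][[f]], assign_fold[[2]][[f]])
        train <- c(unlist(assign_fold[[1]][-f], use.names = FALSE),
                   unlist(assign_fold[[2]][-f], use.names = FALSE))
        list(train = sort(train), test = sort(test))
      })
    })
  })
  structure(list(k = k, n_repeats = n_repeats, seed = seed,
                 classes = classes, repeats = repeats),
            class = "fold_partition")
}

#' @export
print.fold_partition <- function(x, ...) {
  cat(sprintf("<fold_partition> k = %d, %d repeat(s), classes %s/%s\n",
              x$k, x$n_repeats, x$classes[1], x$classes[2]))
  invisible(x)
}

label01 <- function(y, classes) {
  y <- as.character(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad)) stopf("labels outside the partition's classes: %s",
                         paste(bad, collapse = ", "))
  as.integer(y == classes[2])
}

#' Fit a shrinkage-regularized linear discriminant classifier
#'
#' Closed form: with pooled within-class covariance `S`, the regularized
#' covariance is `S' = (1 - lambda) S + lambda (tr(S)/p) I`; weights are
#' `w = S'^{-1} (mu1 - mu0)` and the bias places the decision threshold at
#' the midpoint of the projected class means, `b = -w . (mu0 + mu1)/2`.
#' Chance level for the balanced two-class problems this package handles is
#' always 0.5.
#'
#' @param X numeric feature matrix, trials x features, no missing values.
#' @param y two-class label vector.
#' @param lambda shrinkage fraction toward the scaled identity, in `[0, 1]`
#'   (default 0.01, the common regularized-LDA default).
#' @return object of class `lda_model` with elements `classes`, `means`,
#'   `w`, `b`, `lambda`, `chance_level`.
#' @export
fit_lda <- function(X, y, lambda = 0.01) {
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stopf("features must be finite")
  check_scalar_number(lambda, "lambda", 0, 1)
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2L) stopf("need exactly 2 classes")
  y01 <- label01(y, classes)
  if (min(table(y01)) < 2L) stopf("need >= 2 training trials per class")
  p <- ncol(X)
  mu0 <- colMeans(X[y01 == 0L, , drop = FALSE])
  mu1 <- colMeans(X[y01 == 1L, , drop = FALSE])
  Z <- rbind(sweep(X[y01 == 0L, , drop = FALSE], 2, mu0),
             sweep(X[y01 == 1L, , drop = FALSE], 2, mu1))
  S <- crossprod(Z) / (nrow(X) - 2)
  Sr <- (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  w <- tryCatch(solve(Sr, mu1 - mu0),
                error = function(e)
                  stopf("pooled covariance is singular (p = %d, n = %d); use lambda > 0",
                        p, nrow(X)))
  b <- -sum(w * (mu0 + mu1)) / 2
  structure(list(classes = classes, means = rbind(class0 = mu0, class1 = mu1),
                 w = as.numeric(w), b = b, lambda = lambda,
                 chance_level = 0.5),
            class = "lda_model")
}

#' Predict from a fitted LDA model
#'
#' Decision value is `x . w + b`; a trial is assigned class1 only when its
#' decision value is strictly positive (ties break toward class0, for
#' reproducibility).
#'
#' @param object an [lda_model][fit_lda].
#' @param newdata trials x features matrix.
#' @param type `"class"` for labels, `"score"` for decision values.
#' @param ... unused.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  if (type == "score") return(s)
  object$classes[(s > 0) + 1L]
}

#' Cross-validated decoding accuracy
#'
#' Unweighted mean, over balancing repeats and folds, of the proportion of
#' correctly classified test trials.
#'
#' @param X trials x features matrix.
#' @param y labels consistent with the partition's classes.
#' @param partition a [balanced_partition] built from `y` (or compatible
#'   labels over the same rows).
#' @param lambda shrinkage parameter passed to the LDA.
#' @param zscore if `TRUE`, features are z-scored fold-wise using the
#'   training rows' mean/SD (reused on the test rows); zero-variance
#'   training features are set to 0.
#' @return accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(X, y, partition, lambda = 0.01, zscore = FALSE) {
  stopifnot(inherits(partition, "fold_partition"))
  X <- as.matrix(X)
  y01 <- label01(y, partition$classes)
  n_needed <- max(vapply(partition$repeats, function(rep)
    max(vapply(rep, function(f) max(f$train, f$test), 0)), 0))
  if (n_needed > nrow(X)) stopf("partition indexes %d rows but X has %d",
                                n_needed, nrow(X))
  cv_accuracy_cpp(X, y01, partition$repeats, lambda, zscore)
}
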