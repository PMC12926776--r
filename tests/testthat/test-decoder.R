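test_that("balanced partitions stratify, balance and never duplicate trials", {
  y <- rep(c("conflict", "nonconflict"), each = 50)
  p <- balanced_partition(y, k = 10, seed = 4)
  for (f in p$repeats[[1]]) {
    expect_length(f$test, 10)
    expect_equal(sum(y[f$test] == "conflict"), 5)
    expect_equal(sum(y[f$train] == "conflict"), 45)
    expect_length(intersect(f$train, f$test), 0)
  }
  tests <- unlist(lapply(p$repeats[[1]], `[[`, "test"))
  expect_false(any(duplicated(tests)))           # test sets disjoint

  # unequal counts at the published change-detection scale: 163 vs 76
  y2 <- rep(c("nonconflict", "conflict"), c(163, 76))
  p2 <- balanced_partition(y2, k = 10, seed = 4)
  used <- unique(unlist(lapply(p2$repeats[[1]], function(f) c(f$train, f$test))))
  expect_equal(sum(y2[used] == "conflict"), 76)
  expect_equal(sum(y2[used] == "nonconflict"), 76)
  for (f in p2$repeats[[1]]) {
    expect_equal(sum(y2[f$test] == "conflict"), sum(y2[f$test] == "nonconflict"))
    expect_equal(sum(y2[f$train] == "conflict"), sum(y2[f$train] == "nonconflict"))
    expect_false(any(duplicated(c(f$train, f$test))))
  }

  expect_identical(balanced_partition(y2, k = 10, seed = 4),
                   balanced_partition(y2, k = 10, seed = 4))
  expect_error(balanced_partition(rep(c("a", "b"), c(5, 100)), k = 10),
               "smaller k")
})

test_that("LDA closed form: symmetric 1-D boundary and nearest-mean equivalence", {
  set.seed(2)
  x <- matrix(c(rnorm(100, -1), rnorm(100, 1)))
  y <- rep(c("a", "b"), each = 100)
  fit <- fit_lda(x, y, lambda = 0)
  boundary <- -fit$b / fit$w
  expect_lt(abs(boundary - (mean(x[1:100]) + mean(x[101:200])) / 2), 1e-10)

  # identity covariance: equivalent to nearest class mean on a probe grid
  set.seed(3)
  X <- matrix(rnorm(400), 200, 2)
  X[101:200, ] <- X[101:200, ] + 2
  yy <- rep(c("a", "b"), each = 100)
  for (lam in c(0, 0.5, 1)) {
    fit2 <- fit_lda(X, yy, lambda = lam)
    probe <- as.matrix(expand.grid(seq(-2, 4, 0.5), seq(-2, 4, 0.5)))
    pred <- predict(fit2, probe)
    m_a <- colMeans(X[1:100, ]); m_b <- colMeans(X[101:200, ])
    d_a <- rowSums(sweep(probe, 2, m_a)^2)
    d_b <- rowSums(sweep(probe, 2, m_b)^2)
    if (lam == 1) {  # exactly spherical: must match nearest mean
      expect_identical(pred, c("a", "b")[(d_b < d_a) + 1])
    } else {         # near-spherical sample covariance: near-total agreement
      expect_gt(mean(pred == c("a", "b")[(d_b < d_a) + 1]), 0.95)
    }
  }
})

test_that("package LDA predictions equal an independently coded textbook implementation", {
  set.seed(9)
  for (i in 1:10) {
    n <- 60; p <- 8
    Xtr <- matrix(rnorm(n * p), n, p)
    ytr <- rep(c("a", "b"), each = n / 2)
    Xtr[ytr == "b", 1:3] <- Xtr[ytr == "b", 1:3] + 0.8
    Xte <- matrix(rnorm(40 * p), 40, p)
    fit <- fit_lda(Xtr, ytr, lambda = 0.01)
    expect_identical(predict(fit, Xte),
                     as.character(lda_oracle(Xtr, ytr, Xte, 0.01)))
    # and the C++ kernel agrees with the R closed form
    cfit <- conflictMVPA:::lda_train_cpp(Xtr, as.integer(ytr == "b"), 0.01)
    expect_equal(as.numeric(cfit$w), fit$w, tolerance = 1e-10)
    expect_equal(cfit$b, fit$b, tolerance = 1e-10)
    # Woodbury path (p > n) agrees with direct inversion
    Xw <- matrix(rnorm(20 * 50), 20, 50)
    yw <- rep(c(0L, 1L), each = 10)
    cw <- conflictMVPA:::lda_train_cpp(Xw, yw, 0.05)
    dirw <- {
      mu0 <- colMeans(Xw[1:10, ]); mu1 <- colMeans(Xw[11:20, ])
      Z <- rbind(sweep(Xw[1:10, ], 2, mu0), sweep(Xw[11:20, ], 2, mu1))
      S <- crossprod(Z) / 18
      solve(0.95 * S + 0.05 * mean(diag(S)) * diag(50), mu1 - mu0)
    }
    expect_equal(as.numeric(cw$w), as.numeric(dirw), tolerance = 1e-8)
  }
})

test_that("singular covariance without shrinkage is rejected with advice", {
  X <- matrix(rnorm(10 * 20), 10, 20)
  y <- rep(c("a", "b"), each = 5)
  expect_error(fit_lda(X, y, lambda = 0), "lambda > 0")
})

test_that("cross-validated accuracy: separability, chance calibration and closed-form gaussian oracle", {
  # perfectly separated clusters
  set.seed(5)
  X <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
             matrix(rnorm(100, 10, 0.1), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  p <- balanced_partition(y, k = 5, seed = 1)
  expect_equal(cv_accuracy(X, y, p), 1.0)

  # shuffled labels on structureless data: mean accuracy ~ 0.5
  accs <- vapply(1:100, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(40 * 4), 40, 4)
    yn <- sample(rep(c("a", "b"), each = 20))
    cv_accuracy(Xn, yn, balanced_partition(yn, k = 5, seed = s))
  }, 0.0)
  expect_lt(abs(mean(accs) - 0.5), 0.03)

  # one informative feature at Cohen's d = 1.5: accuracy ~ Phi(d/2)
  accs2 <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 200
    Xg <- cbind(c(rnorm(n / 2, 0), rnorm(n / 2, 1.5)))
    yg <- rep(c("a", "b"), each = n / 2)
    cv_accuracy(Xg, yg, balanced_partition(yg, k = 10, seed = s))
  }, 0.0)
  expect_lt(abs(mean(accs2) - pnorm(1.5 / 2)), 0.05)
})

test_that("cv accuracy is invariant to affine feature maps (lambda = 0) and matches a manual fold loop", {
  set.seed(8)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c("a", "b"), each = 30)
  X[y == "b", ] <- X[y == "b", ] + 0.5
  p <- balanced_partition(y, k = 5, seed = 2)
  a1 <- cv_accuracy(X, y, p, lambda = 0)
  A <- matrix(rnorm(16), 4, 4)  # invertible w.p. 1
  a2 <- cv_accuracy(X %*% A + 3, y, p, lambda = 0)
  expect_equal(a1, a2, tolerance = 1e-8)

  # manual loop over the same folds using the R-level fit/predict path
  manual <- mean(vapply(p$repeats[[1]], function(f) {
    fit <- fit_lda(X[f$train, ], y[f$train], lambda = 0.01)
    mean(predict(fit, X[f$test, ]) == y[f$test])
  }, 0.0))
  expect_equal(cv_accuracy(X, y, p, lambda = 0.01), manual, tolerance = 1e-12)
})
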