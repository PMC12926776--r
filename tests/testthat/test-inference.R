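test_that("TFCE basics: zeros, height monotonicity, worked 1-D example", {
  expect_equal(tfce(rep(0, 7)), rep(0, 7))
  v <- c(0, 1, 2, 3, 2, 1, 0)
  enh <- tfce(v)
  brute <- tfce_bruteforce(v, chain_edges(7))
  expect_equal(enh, brute, tolerance = 1e-9)
  enh2 <- tfce(2 * v)
  expect_true(all(enh2[v > 0] > enh[v > 0]))
  expect_error(tfce(c(1, NA, 2)), "finite")
  # symmetric-adjacency contract
  adj <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(tfce(c(1, 2), neighborhood = adj), "symmetric")
})

test_that("TFCE equals the brute-force threshold sum on random 1-D and 2-D maps", {
  set.seed(42)
  worst <- 0
  for (i in 1:60) {
    v <- rnorm(25, sd = 1.5)
    worst <- max(worst, max(abs(tfce(v) - tfce_bruteforce(v, chain_edges(25)))))
  }
  for (i in 1:40) {
    m <- matrix(rnorm(49, sd = 1.5), 7, 7)
    worst <- max(worst, max(abs(tfce(m) -
      matrix(tfce_bruteforce(m, lattice_edges(c(7, 7))), 7, 7))))
  }
  expect_lt(worst, 1e-9)
})

test_that("two-tailed TFCE is the signed combination of both tails", {
  v <- c(-2, -1, 0, 1, 2, 3)
  two <- tfce(v, tails = "two")
  expect_equal(two, tfce(v) - tfce(-v), tolerance = 1e-12)
  expect_lt(two[1], 0)
  expect_gt(two[6], 0)
})

test_that("graph neighborhoods connect channels spatially and along steps", {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE
  ed <- graph_time_edges(adj, 2)
  # 1 spatial edge per step + 3 temporal edges
  expect_equal(nrow(ed), 2 + 3)
  expect_error(graph_time_edges(matrix(c(FALSE, TRUE, FALSE, FALSE), 2), 2),
               "symmetric")
})

test_that("sign-flip cluster inference flags a strong localized group effect with correct extent", {
  set.seed(31)
  times <- seq(0, 396, 4)
  n_sub <- 14
  inside <- times >= 120 & times <= 240
  maps <- lapply(1:n_sub, function(s)
    decoding_map(0.5 + inside * 0.12 + rnorm(length(times), 0, 0.02),
                 list(time = times)))
  ci <- montecarlo_cluster_stat(maps, n_iter = 500, seed = 2)
  expect_s3_class(ci, "cluster_inference")
  expect_gt(nrow(ci$clusters), 0)
  main <- ci$clusters[which.max(ci$clusters$n_cells), ]
  expect_lt(abs(main$time_start - 120), 12)
  expect_lt(abs(main$time_end - 240), 12)
  # grid mismatch contract
  bad <- c(maps, list(decoding_map(rep(0.5, 10), list(time = 1:10))))
  expect_error(montecarlo_cluster_stat(bad), "identical grids")
})

test_that("degenerate zero-variance maps take the sentinel path and come out significant", {
  m <- matrix(rep(0.6, 8 * 20), 8, 20)  # identical, strictly above chance
  ci <- montecarlo_cluster_stat(m, n_iter = 300, seed = 3)
  expect_true(all(ci$mask))
  expect_true(all(is.finite(ci$tfce_map)))
})

test_that("resampled accuracy null: dominance, midrank ties, and the CLT oracle", {
  perms <- matrix(0.5, 5, 10)
  expect_equal(stelzer_null(0.9, perms, n_draws = 1000)$percentile, 100)
  expect_equal(stelzer_null(0.5, perms, n_draws = 1000)$percentile, 50)

  set.seed(8)
  n_sub <- 30
  P <- matrix(rnorm(n_sub * 100, 0.5, 0.01), n_sub, 100)
  obs <- 0.5009
  nul <- stelzer_null(obs, P, n_draws = 2e5, seed = 4)
  # analytic oracle from the empirical permutation sets
  mu <- mean(rowMeans(P))
  v <- mean(apply(P, 1, function(r) mean((r - mean(r))^2)))
  z <- (obs - mu) / sqrt(v / n_sub)
  expect_lt(abs(nul$percentile - 100 * pnorm(z)), 0.7)
  expect_error(stelzer_null(0.5, matrix(0.5, 5, 1)), "at least 2")
})

test_that("JZS Bayes factor: reciprocal identity, monotonicity, null-favoring at t = 0, quadrature oracle", {
  # independent oracle: fixed-grid Simpson integration on u = g/(1+g)
  bf_oracle <- function(t, n, r = sqrt(2) / 2, ngrid = 200001) {
    nu <- n - 1
    u <- seq(1e-9, 1 - 1e-9, length.out = ngrid)
    g <- u / (1 - u)
    jac <- 1 / (1 - u)^2
    lr <- -0.5 * log1p(n * g) -
      (nu + 1) / 2 * (log1p(t^2 / ((1 + n * g) * nu)) - log1p(t^2 / nu))
    lp <- 0.5 * log(r^2 / (2 * pi)) - 1.5 * log(g) - r^2 / (2 * g)
    f <- exp(lr + lp) * jac
    h <- u[2] - u[1]
    w <- rep(c(4, 2), length.out = ngrid - 2)
    h / 3 * (f[1] + f[ngrid] + sum(w * f[2:(ngrid - 1)]))
  }
  for (case in list(c(3, 30), c(1.2, 12), c(6.14, 507), c(0.3, 80))) {
    ours <- bf10_ttest(t = case[1], n = case[2])
    expect_lt(abs(ours - bf_oracle(case[1], case[2])) / ours, 1e-6)
  }
  expect_equal(bf10_ttest(t = 2.1, n = 25) * (1 / bf10_ttest(t = 2.1, n = 25)),
               1)
  expect_equal(bf10_ttest(t = -3, n = 30), bf10_ttest(t = 3, n = 30))
  bfs <- vapply(c(0, 0.5, 1, 2, 4), function(t) bf10_ttest(t = t, n = 24), 0.0)
  expect_true(all(diff(bfs) > 0))
  expect_lt(bf10_ttest(t = 0, n = 10), 1)
  expect_error(bf10_ttest(t = Inf, n = 10), "finite")
  expect_error(bf10_ttest(x = c(1, 1, 1)), "zero variance")
})

test_that("evidence bands split at 1/3, 3, 20 and 150", {
  expect_equal(as.character(bf_band(c(0.2, 2.9, 3.1, 50, 200))),
               c("supports_null", "inconclusive", "substantial", "strong",
                 "very_strong"))
})

test_that("per-cell Bayes factors favor the null at t = 0 and the effect inside a strong cluster", {
  set.seed(12)
  n_sub <- 20
  M <- matrix(0.5, n_sub, 6)
  M[, 1:3] <- 0.5 + matrix(rnorm(n_sub * 3, 0.1, 0.02), n_sub, 3)
  M[, 4:6] <- 0.5 + matrix(rnorm(n_sub * 3, 0, 0.02), n_sub, 3)
  bt <- bf_timecourse(M)
  expect_true(all(bt$bf10[1:3] > 3))
  expect_true(all(bt$bf10[4:6] < 3))
  # all subjects exactly at chance in a cell -> zero variance is an error by
  # construction of the t statistic, so jitter-free columns are the caller's
  # responsibility; a tiny-variance chance column favors the null
  Mc <- cbind(M[, 4] * 0 + 0.5 + rnorm(n_sub, 0, 1e-6))
  expect_lt(bf_timecourse(Mc)$bf10, 1)
})

test_that("paired comparisons reproduce the d_av definition and reject zero-variance input", {
  set.seed(3)
  x <- rnorm(40, 10, 2)
  y <- rnorm(40, 9, 2)
  es <- effect_summary(x, y)
  expect_equal(es$d_av, abs(mean(x) - mean(y)) / ((sd(x) + sd(y)) / 2))
  expect_equal(es$bf10 * es$bf01, 1)
  expect_equal(es$df, 39)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(es$t, unname(tt$statistic))
  expect_error(effect_summary(x, x), "zero variance")
})
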