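# Shared fixtures: all synthetic data are generated in code, scaled down to
# keep the suite fast while preserving the structure of the full designs.

# compact two-task config: A carries the shared pattern, B an orthogonal one
tiny_config <- function(n_subjects = 1, seed = 11, alpha_b = 0,
                        n_con = 30, n_non = 30, amp = 1.5, theta = 1,
                        window = c(-100, 1100)) {
  synth_config(
    tasks = list(
      task_recipe("A", epoch_window = window, n_conflict = n_con,
                  n_nonconflict = n_non, evoked_amplitude = amp,
                  theta_amplitude = theta, overlap_alpha = 1),
      task_recipe("B", epoch_window = window, n_conflict = n_con,
                  n_nonconflict = n_non, evoked_amplitude = amp,
                  theta_amplitude = theta, overlap_alpha = alpha_b)),
    n_subjects = n_subjects, seed = seed)
}

# epoch set built directly (no generator): Gaussian noise plus an optional
# per-timepoint conflict shift along `pattern`, for construction-level tests
make_epochs <- function(n_con = 30, n_non = 30, n_ch = 8, times = seq(0, 396, 4),
                        pattern = NULL, effect = 0, seed = 1,
                        task_id = "toy") {
  set.seed(seed)
  n_tr <- n_con + n_non
  n_ti <- length(times)
  if (is.null(pattern)) pattern <- rep(0, n_ch)
  if (length(effect) == 1) effect <- rep(effect, n_ti)
  dat <- array(rnorm(n_tr * n_ch * n_ti), c(n_tr, n_ch, n_ti))
  cond <- rep(c("conflict", "nonconflict"), c(n_con, n_non))
  for (tr in which(cond == "conflict"))
    dat[tr, , ] <- dat[tr, , ] + outer(pattern, effect)
  epoch_set(dat, times, 1000 / diff(times[1:2]), paste0("ch", seq_len(n_ch)),
            data.frame(condition = cond,
                       response_hand = sample(c("left", "right"), n_tr, TRUE),
                       rt_ms = rlnorm(n_tr, log(500), 0.2),
                       correct = rbinom(n_tr, 1, 0.9)),
            task_id = task_id)
}

# brute-force TFCE oracle: explicit loop over thresholds with components
# found by flood fill over the edge list (independent of the union-find path)
tfce_bruteforce <- function(values, edges, E = 0.5, H = 2, dh = 0.1) {
  v <- as.numeric(values)
  n <- length(v)
  out <- numeric(n)
  vmax <- max(v)
  if (vmax <= 0) return(out)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  for (h in seq_len(floor(vmax / dh + 1e-9)) * dh) {
    active <- v >= h
    seen <- rep(FALSE, n)
    for (s in which(active)) {
      if (seen[s]) next
      comp <- integer(0)
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        node <- queue[1]; queue <- queue[-1]
        comp <- c(comp, node)
        nb <- adj[[node]]
        nb <- nb[active[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      out[comp] <- out[comp] + length(comp)^E * h^H * dh
    }
  }
  out
}

# textbook shrinkage-LDA oracle written long-hand, kept independent of the
# package implementation
lda_oracle <- function(Xtr, ytr, Xte, lambda) {
  cls <- sort(unique(ytr))
  X0 <- Xtr[ytr == cls[1], , drop = FALSE]
  X1 <- Xtr[ytr == cls[2], , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  p <- ncol(Xtr)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    (nrow(Xtr) - 2)
  Sr <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(p)
  w <- solve(Sr) %*% (mu1 - mu0)
  scores <- Xte %*% w - as.numeric(crossprod(w, (mu0 + mu1) / 2))
  cls[(scores > 0) + 1]
}
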