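#' Derive a reproducible sub-seed
#'
#' Fans a single user-facing seed out to independent per-stage / per-unit
#' seeds by hashing the seed together with a sequence of string or integer
#' tags. The hash is a simple 32-bit multiplicative mix over the UTF-8 bytes
#' of the tags, kept strictly below `2^31 - 1` so the result is always a
#' valid R integer seed. Deterministic across platforms and R versions.
#'
#' @param seed integer master seed.
#' @param ... tags (character or numeric) identifying the consumer, e.g.
#'   `derive_seed(1, "simulate", subject, task)`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- vapply(list(...), function(x) paste(format(x, scientific = FALSE), collapse = "|"),
                 character(1))
  bytes <- utf8ToInt(paste(c(format(seed, scientific = FALSE), tags), collapse = "/"))
  h <- 2166136261
  m <- 2^31 - 1
  for (b in bytes) {
    h <- (h * 16777619) %% m
    h <- bitwXor(as.integer(h), as.integer(b))
  }
  as.integer(h %% m)
}

#' Evaluate with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never perturb user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# shared input checks -------------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

#' @keywords internal
unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}
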