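# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All exported generators route randomness through this so that no function
# mutates the global random state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer.", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-chain (or per-replicate) seeds from a master seed, keeping them
# inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_fcg <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw from N(mean, sd^2) truncated to [lo, hi] by resampling.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
    if (guard > 10000L) { # essentially impossible mass in [lo, hi]
      out[bad] <- min(max(mean, lo), hi)
      break
    }
  }
  out
}

half_cauchy_lpdf <- function(x, scale) {
  if (any(x <= 0)) return(-Inf)
  sum(log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
}
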