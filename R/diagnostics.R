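# MCMC convergence diagnostics: split R-hat and a Geyer initial-positive-
# sequence effective sample size, computed per stored scalar.

#' Split R-hat for one scalar across chains
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' statistic is computed over the resulting half-chains, so within-chain
#' drift also inflates the diagnostic.
#'
#' @param chains List of numeric vectors, one per chain (equal lengths).
#' @return Scalar R-hat (NA if draws are constant).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(length(x) - n + 1L):length(x)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  Bn <- stats::var(means)           # between-half-chain variance of means
  if (!is.finite(W) || W == 0) return(if (Bn == 0) 1 else NA_real_)
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Effective sample size across chains
#'
#' Per-chain Geyer initial-positive-sequence estimate from the empirical
#' autocorrelations, summed over chains.
#'
#' @param chains List of numeric vectors, one per chain.
#' @return Scalar ESS.
#' @export
ess_chains <- function(chains) {
  sum(vapply(chains, function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                      demean = TRUE)$acf[-1]
    s <- 0; k <- 1L
    while (k <= length(rho) - 1L) {
      pair <- rho[k] + rho[k + 1L]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2L
    }
    n / (1 + 2 * s)
  }, numeric(1)))
}
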