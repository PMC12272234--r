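# Instrument layout of the four maternal mental-health scores: legal score
# ranges and the means/SDs of the emulated cohort (its descriptive summary).
mh_instruments <- function() {
  data.frame(
    instrument = c("epds", "pss", "stai_state", "stai_trait"),
    lo = c(0, 0, 20, 20), hi = c(30, 56, 80, 80),
    mean = c(4.21, 15.59, 29.34, 30.79),
    sd = c(3.38, 7.02, 9.27, 8.42))
}

# Moments of a normal N(m, s^2) clamped to [lo, hi]; closed form via
# truncated-normal pieces. Vectorized over m.
clamped_normal_moments <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  Pa <- pnorm(a); Pb <- pnorm(b); pa <- dnorm(a); pb <- dnorm(b)
  E1 <- lo * Pa + hi * (1 - Pb) + m * (Pb - Pa) + s * (pa - pb)
  E2 <- lo^2 * Pa + hi^2 * (1 - Pb) + m^2 * (Pb - Pa) +
    2 * m * s * (pa - pb) + s^2 * ((Pb - Pa) + a * pa - b * pb)
  cbind(E1, E2)
}

# Deterministic large-n PC1 variance-explained implied by a one-factor model
# with per-item loadings `lam` after each item is clamped to its instrument
# range. Integrates over the latent factor on a fine normal grid; conditional
# on the factor the items are independent with closed-form clamped moments.
mh_implied_ve <- function(lam, inst) {
  fg <- seq(-8, 8, length.out = 401)
  w <- dnorm(fg); w <- w / sum(w)
  p <- nrow(inst)
  M <- matrix(0, length(fg), p); E2 <- numeric(p)
  for (k in seq_len(p)) {
    mom <- clamped_normal_moments(inst$mean[k] + inst$sd[k] * lam[k] * fg,
                                  inst$sd[k] * sqrt(1 - lam[k]^2),
                                  inst$lo[k], inst$hi[k])
    M[, k] <- mom[, 1]
    E2[k] <- sum(w * mom[, 2])
  }
  mu <- colSums(w * M)
  V <- E2 - mu^2
  CC <- t(M * w) %*% M - outer(mu, mu)
  R <- CC / sqrt(outer(V, V)); diag(R) <- 1
  eigen(R, symmetric = TRUE, only.values = TRUE)$values[1] / p
}

#' Simulate maternal mental-health instrument scores
#'
#' Generates EPDS, PSS, STAI-state and STAI-trait totals from a one-factor
#' model: each standardized item is \eqn{\lambda_k f + \sqrt{1-\lambda_k^2}
#' e_k} with a shared factor \eqn{f} and independent noise, rescaled to the
#' emulated cohort's instrument means and SDs, clamped into each
#' instrument's legal range (EPDS 0-30, PSS 0-56, STAI 20-80) and rounded to
#' integers. The common factor strength is calibrated deterministically
#' (numerical integration over the factor with closed-form clamped-normal
#' moments) so that, for large n, the first principal component of the
#' scaled data explains \code{var_explained_target} of the total variance.
#' Rounding is ignored by the calibration; its attenuation is of order 1e-3.
#'
#' @param n_subjects Number of subjects.
#' @param loading_vector Relative factor loadings of the four instruments
#'   (unit norm; default equal).
#' @param var_explained_target Target PC1 variance-explained in (0.25, 1].
#' @param seed Integer seed.
#' @param integerize Clamp to instrument ranges and round to integers
#'   (default). Disable to obtain the raw continuous factor-model draws (a
#'   target of 1 then yields exactly rank-1 data).
#' @return data.frame with columns \code{subject_id}, \code{epds},
#'   \code{pss}, \code{stai_state}, \code{stai_trait}.
#' @examples
#' mh <- simulate_mental_health(29, seed = 1)
#' range(mh$epds)  # within [0, 30]
#' @export
simulate_mental_health <- function(n_subjects,
                                   loading_vector = rep(0.5, 4),
                                   var_explained_target = 0.73, seed,
                                   integerize = TRUE) {
  inst <- mh_instruments()
  w <- as.numeric(loading_vector)
  if (length(w) != 4 || any(w <= 0))
    stop("`loading_vector` must be 4 positive loadings.")
  if (abs(sqrt(sum(w^2)) - 1) > 1e-6)
    stop("`loading_vector` must have unit norm.")
  ve <- var_explained_target
  if (!is.numeric(ve) || ve <= 0.25 || ve > 1)
    stop("`var_explained_target` must be in (0.25, 1].")
  wn <- w / max(w)                     # scale so s in (0,1] maps to max loading
  lam_of <- function(s) pmin(wn * s, 1 - 1e-12)
  if (ve >= 1 - 1e-9) {
    if (any(abs(wn - 1) > 1e-9) || integerize)
      stop(paste0("a variance-explained target of 1 is only feasible with ",
                  "equal loadings and `integerize = FALSE`."))
    lam <- rep(1, 4)
  } else if (!integerize) {
    # no clamping: implied correlation is lam_j lam_k exactly
    f <- function(s) {
      lam <- lam_of(s)
      R <- outer(lam, lam); diag(R) <- 1
      eigen(R, symmetric = TRUE, only.values = TRUE)$values[1] / 4 - ve
    }
    if (f(1 - 1e-6) < 0) stop("`var_explained_target` infeasible for these loadings.")
    lam <- lam_of(stats::uniroot(f, c(1e-4, 1 - 1e-6), tol = 1e-9)$root)
  } else {
    f <- function(s) mh_implied_ve(lam_of(s), inst) - ve
    if (f(1 - 1e-4) < 0)
      stop("`var_explained_target` infeasible for these loadings after range clamping.")
    lam <- lam_of(stats::uniroot(f, c(1e-4, 1 - 1e-4), tol = 1e-7)$root)
  }
  with_seed(seed, {
    fscore <- rnorm(n_subjects)
    X <- sapply(seq_len(4), function(k) {
      z <- lam[k] * fscore + sqrt(max(0, 1 - lam[k]^2)) * rnorm(n_subjects)
      x <- inst$mean[k] + inst$sd[k] * z
      if (integerize) round(pmin(pmax(x, inst$lo[k]), inst$hi[k])) else x
    })
    X <- matrix(X, nrow = n_subjects)
    out <- data.frame(subject_id = sprintf("fet_%02d", seq_len(n_subjects)),
                      X)
    names(out)[-1] <- inst$instrument
    out
  })
}
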