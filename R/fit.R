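#' Prior settings for the growth model
#'
#' Gaussian priors are used for location parameters and half-Cauchy priors
#' for standard deviations, with scales chosen to be nearly flat over
#' plausible Fisher-z values. The spline coefficients carry both the
#' second-difference roughness penalty \eqn{D\beta \sim N(0, \tau^2 I)} and
#' a diffuse \eqn{N(0, s_\beta^2 I)} that makes the two directions the
#' penalty leaves flat (overall level and slope) proper.
#'
#' @param coef_sd Diffuse SD \eqn{s_\beta} on spline coefficients.
#' @param offset_sd SD \eqn{s_\delta} of cohort-offset priors.
#' @param covariate_sd SD \eqn{s_\gamma} of the covariate-slope prior.
#' @param tau_scale Half-Cauchy scale of the penalty SD \eqn{\tau}.
#' @param sigma_a_scale Half-Cauchy scale of the random-intercept SD.
#' @param sigma_b_scale Half-Cauchy scale of the random-slope SD (smaller,
#'   since per-week slopes are small on the Fisher-z scale).
#' @param sigma_scale Half-Cauchy scale of the per-cohort residual SDs.
#' @return List of class \code{"growth_prior"}.
#' @export
growth_prior <- function(coef_sd = 10, offset_sd = 1, covariate_sd = 1,
                         tau_scale = 1, sigma_a_scale = 1,
                         sigma_b_scale = 0.25, sigma_scale = 1) {
  p <- list(coef_sd = coef_sd, offset_sd = offset_sd,
            covariate_sd = covariate_sd, tau_scale = tau_scale,
            sigma_a_scale = sigma_a_scale, sigma_b_scale = sigma_b_scale,
            sigma_scale = sigma_scale)
  if (any(unlist(p) <= 0)) stop("all prior scales must be > 0.")
  class(p) <- "growth_prior"
  p
}

# Canonical internal ordering: subjects ordered by their data content
# (cohort, then sorted ages and values), rows within subject by (age, value).
# This makes every posterior summary invariant to subject relabelling and to
# row permutations of the input, for a fixed seed.
canonical_order <- function(subject, cohort, t, y) {
  key <- vapply(split(seq_along(t), subject), function(idx) {
    o <- order(t[idx], y[idx])
    paste(cohort[idx][1],
          paste(sprintf("%.12g", t[idx][o]), collapse = ","),
          paste(sprintf("%.12g", y[idx][o]), collapse = ","))
  }, character(1))
  subj_rank <- rank(key, ties.method = "first")
  ord <- order(subj_rank[match(subject, names(key))], t, y)
  ord
}

#' Fit the Bayesian penalized B-spline growth model
#'
#' Models a longitudinal connectivity measure as a smooth function of
#' postmenstrual age with subject- and cohort-level structure:
#' \deqn{y_{ij} \sim N\big(B(t_{ij})\beta + \delta_{c(i)} + a_i +
#'   b_i (t_{ij} - t_0) + \gamma x_i,\; \sigma^2_{c(i)}\big)}
#' where \eqn{B} is a B-spline basis with a knot at every week of PMA from
#' 30 through 44 (cubic, K = 17), the second differences of \eqn{\beta}
#' carry a Gaussian penalty with estimated SD \eqn{\tau}, subjects have
#' random intercepts and slopes, each cohort has an additive offset
#' (reference cohort fixed at 0, so the fitted mean curve is the reference
#' cohort's trajectory) and its own residual SD, and \eqn{\gamma} is an
#' optional linear effect of a standardized subject-level covariate.
#' Standard deviations have half-Cauchy priors (sampled via an
#' inverse-gamma auxiliary-variable representation, which keeps every full
#' conditional conjugate), and the model is fitted by Gibbs sampling.
#'
#' @param formula Two-sided formula \code{value ~ age} naming the response
#'   and the PMA column of \code{data}.
#' @param data data.frame of per-scan observations.
#' @param subject,cohort Names of the subject-id and cohort columns.
#' @param covariate Optional subject-level covariate: a two-column
#'   data.frame (subject id, score). Scores are standardized across the
#'   subjects present in \code{data}; scans of subjects without a score are
#'   excluded from the fit and counted in the result.
#' @param reference Reference cohort (offset fixed at 0). Default: the
#'   cohort spanning the widest age range, which for the emulated design is
#'   the longitudinal fetal-neonatal cohort.
#' @param basis A \code{\link{growth_basis}} specification.
#' @param t0 Centering age (weeks) of the random slopes.
#' @param prior A \code{\link{growth_prior}}.
#' @param chains,warmup,iter,thin Sampler layout: retained draws per chain
#'   are \code{iter} after \code{warmup} adaptation sweeps, thinned by
#'   \code{thin}.
#' @param seed Integer seed; chain seeds are derived from it.
#' @param random_effects Set \code{FALSE} to drop subject random effects
#'   (used for degenerate conjugate checks).
#' @param fix Optional list fixing variance parameters at known values
#'   instead of sampling them: any of \code{tau}, \code{sigma} (residual
#'   SD, scalar or named per cohort), \code{sigma_a}, \code{sigma_b}.
#' @param verbose Print per-chain progress.
#' @return Object of class \code{"pspline_growth"} with posterior draws,
#'   convergence diagnostics (split R-hat and effective sample size for
#'   every stored scalar), random-effect posterior means, and the data in
#'   canonical order. A warning of class \code{"fcg_convergence_warning"}
#'   is raised when any R-hat exceeds 1.01 or any ESS falls below 400.
#' @export
pspline_growth <- function(formula, data, subject = "subject_id",
                           cohort = "cohort", covariate = NULL,
                           reference = NULL, basis = growth_basis(),
                           t0 = 37, prior = growth_prior(),
                           chains = 4, warmup = 2000, iter = 2000, thin = 1,
                           seed = 1, random_effects = TRUE, fix = list(),
                           verbose = FALSE) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = NULL)
  if (ncol(mf) != 2) stop("`formula` must be of the form value ~ age.")
  y <- as.numeric(mf[[1]]); t <- as.numeric(mf[[2]])
  if (any(!is.finite(y)) || any(!is.finite(t)))
    stop("non-finite response or age values.")
  if (length(y) > 1 && stats::sd(y) == 0)
    stop(paste0("the response is constant; the growth model is degenerate ",
                "without any variation."))
  subj <- as.character(data[[subject]])
  coh <- as.character(data[[cohort]])
  if (is.null(subj) || is.null(coh))
    stop("`subject`/`cohort` columns not found in `data`.")

  # covariate handling: subject-level, standardized; scans without it dropped
  x_by_subj <- NULL; n_dropped_cov <- 0L
  if (!is.null(covariate)) {
    covariate <- as.data.frame(covariate)
    if (ncol(covariate) < 2) stop("`covariate` needs (subject, score) columns.")
    x_raw <- stats::setNames(as.numeric(covariate[[2]]),
                             as.character(covariate[[1]]))
    have <- subj %in% names(x_raw)[is.finite(x_raw)]
    n_dropped_cov <- length(unique(subj[!have]))
    y <- y[have]; t <- t[have]; coh <- coh[have]; subj <- subj[have]
    if (!length(y)) stop("no scans with covariate data remain.")
    xs <- x_raw[unique(subj)]
    if (stats::sd(xs) == 0) stop("covariate has zero variance.")
    x_by_subj <- (x_raw - mean(xs)) / stats::sd(xs)
  }

  if (length(unique(subj)) < 2) stop("need at least 2 subjects.")
  ord <- canonical_order(subj, coh, t, y)
  y <- y[ord]; t <- t[ord]; coh <- coh[ord]; subj <- subj[ord]

  cohorts <- unique(coh)
  if (is.null(reference)) {
    span <- vapply(split(t, coh), function(v) diff(range(v)), numeric(1))
    reference <- names(which.max(span))
  }
  if (!reference %in% cohorts) stop("`reference` cohort absent from data.")
  cohorts <- c(reference, setdiff(sort(cohorts), reference))
  cidx <- match(coh, cohorts)
  sids <- unique(subj)
  sidx <- match(subj, sids)
  x_subj <- if (is.null(x_by_subj)) NULL else as.numeric(x_by_subj[sids])

  B <- build_basis(t, basis)
  K <- ncol(B)
  D <- second_difference_matrix(K)
  u <- t - t0

  fit <- gibbs_growth(y, B, D, cidx, sidx, u, x_subj, cohorts, prior,
                      chains = chains, warmup = warmup, iter = iter,
                      thin = thin, seed = seed,
                      random_effects = random_effects, fix = fix,
                      verbose = verbose)

  out <- structure(list(
    call = cl, draws = fit$draws, parameters = fit$parameters,
    diagnostics = fit$diagnostics, ranef = fit$ranef,
    basis = basis, D = D, t0 = t0, prior = prior,
    reference = reference, cohorts = cohorts,
    data = data.frame(subject_id = subj, cohort = coh, pma_weeks = t,
                      value = y, stringsAsFactors = FALSE),
    subjects = sids, covariate = x_subj,
    n_dropped_covariate = n_dropped_cov,
    settings = list(chains = chains, warmup = warmup, iter = iter,
                    thin = thin, seed = seed,
                    random_effects = random_effects, fix = fix)),
    class = "pspline_growth")
  dg <- out$diagnostics
  if (any(dg$rhat > 1.01, na.rm = TRUE) || any(dg$ess < 400, na.rm = TRUE))
    warning(structure(class = c("fcg_convergence_warning", "warning",
                                "condition"),
                      list(message = paste0(
                        "convergence diagnostics outside targets (max R-hat ",
                        sprintf("%.3f", max(dg$rhat, na.rm = TRUE)),
                        ", min ESS ", sprintf("%.0f", min(dg$ess,
                                                          na.rm = TRUE)),
                        "); consider longer chains."), call = NULL)))
  out
}

# The Gibbs sampler. All full conditionals are conjugate; half-Cauchy priors
# on SDs use the inverse-gamma mixture representation
# sigma^2 ~ IG(1/2, 1/eta), eta ~ IG(1/2, 1/A^2)  <=>  sigma ~ C+(0, A).
gibbs_growth <- function(y, B, D, cidx, sidx, u, x_subj, cohorts, prior,
                         chains, warmup, iter, thin, seed, random_effects,
                         fix, verbose) {
  N <- length(y); K <- ncol(B); C <- length(cohorts)
  S <- max(sidx)
  DtD <- crossprod(D)
  has_cov <- !is.null(x_subj)
  xrow <- if (has_cov) x_subj[sidx] else numeric(N)
  n_c <- tabulate(cidx, C)

  fix_sigma <- NULL
  if (!is.null(fix$sigma)) {
    fs <- fix$sigma
    fix_sigma <- if (length(fs) == 1 && is.null(names(fs)))
      rep(as.numeric(fs), C) else as.numeric(fs[cohorts])
    if (any(!is.finite(fix_sigma))) stop("fix$sigma must cover every cohort.")
  }

  par_names <- c(paste0("beta[", seq_len(K), "]"),
                 if (C > 1) paste0("delta[", cohorts[-1], "]"),
                 if (has_cov) "gamma",
                 "tau",
                 if (random_effects) c("sigma_a", "sigma_b"),
                 paste0("sigma[", cohorts, "]"))
  P <- length(par_names)
  chain_seeds <- derive_seeds(seed, chains)
  draws <- vector("list", chains)
  ranef_acc <- matrix(0, S, 2)

  for (ch in seq_len(chains)) {
    with_seed(chain_seeds[ch], {
      # initial values
      sig2 <- if (!is.null(fix_sigma)) fix_sigma^2 else
        pmax(vapply(split(y, cidx), stats::var, numeric(1))[as.character(seq_len(C))],
             1e-4)
      sig2[is.na(sig2)] <- stats::var(y)
      tau2 <- if (!is.null(fix$tau)) fix$tau^2 else 0.01
      sa2 <- if (!is.null(fix$sigma_a)) fix$sigma_a^2 else 0.0025
      sb2 <- if (!is.null(fix$sigma_b)) fix$sigma_b^2 else 1e-4
      eta_s <- rep(1, C); eta_t <- 1; eta_a <- 1; eta_b <- 1
      a <- rep(0, S); b <- rep(0, S); delta <- rep(0, C); gamma <- 0
      A0 <- crossprod(B) / max(sig2) + DtD / tau2 + diag(1 / prior$coef_sd^2, K)
      beta <- drop(solve(A0, crossprod(B, y / max(sig2))))
      Bb <- drop(B %*% beta)

      n_keep <- iter
      M <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, par_names))
      total <- warmup + iter * thin
      kept <- 0L
      # fixed-effect design: spline columns, non-reference cohort
      # indicators, optional covariate. Updated as one Gaussian block so the
      # curve level does not random-walk against the offsets.
      Zc <- if (C > 1) outer(cidx, 2:C, `==`) * 1 else NULL
      X <- cbind(B, Zc, if (has_cov) xrow)
      Kx <- ncol(X)
      prior_prec_fixed <- diag(c(rep(1 / prior$coef_sd^2, K),
                                 rep(1 / prior$offset_sd^2, max(C - 1, 0)),
                                 if (has_cov) 1 / prior$covariate_sd^2),
                               Kx)
      Dx <- cbind(D, matrix(0, nrow(D), Kx - K))

      for (it in seq_len(total)) {
        w <- 1 / sig2[cidx]
        re <- a[sidx] + b[sidx] * u

        # joint draw of (beta, delta, gamma)
        r <- y - re
        A <- crossprod(X, X * w) + crossprod(Dx) / tau2 + prior_prec_fixed
        ch_A <- chol(A)
        mvec <- backsolve(ch_A, forwardsolve(t(ch_A), crossprod(X, r * w)))
        theta <- drop(mvec + backsolve(ch_A, rnorm(Kx)))
        beta <- theta[seq_len(K)]
        if (C > 1) delta <- c(0, theta[(K + 1):(K + C - 1)])
        if (has_cov) gamma <- theta[Kx]
        Bb <- drop(B %*% beta)
        gx <- if (has_cov) gamma * xrow else 0

        # subject random intercepts and slopes, jointly per subject
        if (random_effects) {
          r4 <- y - Bb - delta[cidx] - gx
          Ssum <- rowsum(cbind(w, w * u, w * u^2, w * r4, w * u * r4), sidx,
                         reorder = TRUE)
          P11 <- Ssum[, 1] + 1 / sa2
          P12 <- Ssum[, 2]
          P22 <- Ssum[, 3] + 1 / sb2
          det <- P11 * P22 - P12^2
          ma <- (P22 * Ssum[, 4] - P12 * Ssum[, 5]) / det
          mb <- (P11 * Ssum[, 5] - P12 * Ssum[, 4]) / det
          L11 <- sqrt(P11); L21 <- P12 / L11; L22 <- sqrt(P22 - L21^2)
          # draw ~ N(mean, P^-1) via solving t(L) x = e for lower-tri L
          e1 <- rnorm(S); e2 <- rnorm(S)
          z2 <- e2 / L22
          b <- mb + z2
          a <- ma + (e1 - L21 * z2) / L11
          re <- a[sidx] + b[sidx] * u

          if (is.null(fix$sigma_a)) {
            sa2 <- 1 / rgamma(1, (S + 1) / 2, rate = 1 / eta_a + sum(a^2) / 2)
            eta_a <- 1 / rgamma(1, 1, rate = 1 / prior$sigma_a_scale^2 + 1 / sa2)
          }
          if (is.null(fix$sigma_b)) {
            sb2 <- 1 / rgamma(1, (S + 1) / 2, rate = 1 / eta_b + sum(b^2) / 2)
            eta_b <- 1 / rgamma(1, 1, rate = 1 / prior$sigma_b_scale^2 + 1 / sb2)
          }
        }

        # residual variances per cohort
        if (is.null(fix_sigma)) {
          res <- y - Bb - delta[cidx] - re - gx
          ssr <- rowsum(res^2, cidx, reorder = TRUE)[, 1]
          sig2 <- 1 / rgamma(C, (n_c + 1) / 2, rate = 1 / eta_s + ssr / 2)
          eta_s <- 1 / rgamma(C, 1, rate = 1 / prior$sigma_scale^2 + 1 / sig2)
        }

        # penalty SD
        if (is.null(fix$tau)) {
          dB <- drop(D %*% beta)
          tau2 <- 1 / rgamma(1, (K - 2 + 1) / 2,
                             rate = 1 / eta_t + sum(dB^2) / 2)
          eta_t <- 1 / rgamma(1, 1, rate = 1 / prior$tau_scale^2 + 1 / tau2)
        }

        if (!all(is.finite(beta)) || !all(is.finite(sig2)))
          stop("sampler produced non-finite values; check the data scale.")

        if (it > warmup && (it - warmup) %% thin == 0) {
          kept <- kept + 1L
          M[kept, ] <- c(beta,
                         if (C > 1) delta[-1],
                         if (has_cov) gamma,
                         sqrt(tau2),
                         if (random_effects) c(sqrt(sa2), sqrt(sb2)),
                         sqrt(sig2))
          if (random_effects)
            ranef_acc <- ranef_acc + cbind(a, b)
        }
      }
      draws[[ch]] <- M
    })
    if (verbose) message("chain ", ch, " done")
  }

  ranef <- ranef_acc / (chains * iter)
  colnames(ranef) <- c("intercept", "slope")
  diagnostics <- data.frame(
    parameter = par_names,
    rhat = vapply(par_names, function(p)
      split_rhat(lapply(draws, function(m) m[, p])), numeric(1)),
    ess = vapply(par_names, function(p)
      ess_chains(lapply(draws, function(m) m[, p])), numeric(1)),
    row.names = NULL)
  list(draws = draws, parameters = par_names, diagnostics = diagnostics,
       ranef = ranef)
}

#' Log posterior density of the growth model
#'
#' The joint log density (including all normalizing constants) of data and
#' parameters under the growth model: Gaussian likelihood with per-cohort
#' residual SDs, the second-difference penalty \eqn{D\beta \sim N(0,\tau^2
#' I)}, diffuse Gaussian priors on coefficients, offsets and the covariate
#' slope, Gaussian random effects, and half-Cauchy priors on all SDs.
#' Useful for validating the sampler against independent density code.
#'
#' @param params List with elements \code{beta}, \code{tau}, \code{delta}
#'   (named per non-reference cohort; may be empty), \code{sigma} (named per
#'   cohort), and optionally \code{a}, \code{b}, \code{sigma_a},
#'   \code{sigma_b} (named by subject) and \code{gamma}.
#' @param data data.frame with \code{subject_id}, \code{cohort},
#'   \code{pma_weeks}, \code{value}.
#' @param reference Reference cohort name (offset 0).
#' @param covariate Optional named standardized covariate per subject.
#' @param basis,t0,prior Model settings, as in \code{\link{pspline_growth}}.
#' @return Scalar log density (finite for legal parameters).
#' @export
log_posterior <- function(params, data, reference,
                          covariate = NULL, basis = growth_basis(),
                          t0 = 37, prior = growth_prior()) {
  y <- data$value
  if (any(!is.finite(y))) stop("non-finite data values.")
  B <- build_basis(data$pma_weeks, basis)
  K <- ncol(B)
  D <- second_difference_matrix(K)
  beta <- params$beta
  delta <- stats::setNames(rep(0, 0), character())
  if (!is.null(params$delta)) delta <- params$delta
  dvec <- ifelse(data$cohort == reference, 0, delta[data$cohort])
  sig <- params$sigma[data$cohort]
  a <- if (!is.null(params$a)) params$a[data$subject_id] else 0
  b <- if (!is.null(params$b)) params$b[data$subject_id] else 0
  gx <- if (!is.null(params$gamma) && !is.null(covariate))
    params$gamma * covariate[data$subject_id] else 0
  mu <- drop(B %*% beta) + dvec + a + b * (data$pma_weeks - t0) + gx

  lp <- sum(stats::dnorm(y, mu, sig, log = TRUE))
  lp <- lp + sum(stats::dnorm(drop(D %*% beta), 0, params$tau, log = TRUE))
  lp <- lp + sum(stats::dnorm(beta, 0, prior$coef_sd, log = TRUE))
  if (length(delta))
    lp <- lp + sum(stats::dnorm(delta, 0, prior$offset_sd, log = TRUE))
  if (!is.null(params$gamma))
    lp <- lp + stats::dnorm(params$gamma, 0, prior$covariate_sd, log = TRUE)
  if (!is.null(params$a)) {
    lp <- lp + sum(stats::dnorm(params$a, 0, params$sigma_a, log = TRUE))
    lp <- lp + sum(stats::dnorm(params$b, 0, params$sigma_b, log = TRUE))
    lp <- lp + half_cauchy_lpdf(params$sigma_a, prior$sigma_a_scale)
    lp <- lp + half_cauchy_lpdf(params$sigma_b, prior$sigma_b_scale)
  }
  lp <- lp + half_cauchy_lpdf(params$tau, prior$tau_scale)
  lp <- lp + half_cauchy_lpdf(unname(params$sigma), prior$sigma_scale)
  lp
}
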