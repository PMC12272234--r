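# Posterior estimands: anchored curve values, age contrasts, sign-error
# probabilities and significance flags.

pooled_draws <- function(fit) {
  if (!inherits(fit, "pspline_growth")) stop("`fit` must be a pspline_growth.")
  do.call(rbind, fit$draws)
}

beta_draws <- function(fit) {
  M <- pooled_draws(fit)
  M[, grep("^beta\\[", colnames(M)), drop = FALSE]
}

#' Per-draw mean curve value at an age
#'
#' Evaluates the population mean trajectory (reference cohort, random
#' effects at zero, covariate at its mean) at one PMA for every retained
#' posterior draw: \eqn{\mu(t) = B(t)\beta}.
#'
#' @param fit A fitted \code{\link{pspline_growth}} model.
#' @param age PMA in weeks, within the basis range.
#' @return Numeric vector, one value per pooled posterior draw.
#' @export
curve_at <- function(fit, age) {
  if (length(age) != 1) stop("`age` must be a single value.")
  brow <- build_basis(age, fit$basis, clamp_slack = 0)
  drop(beta_draws(fit) %*% t(brow))
}

#' Per-draw change in the mean curve between two ages
#'
#' @param fit A fitted model.
#' @param age_hi,age_lo Ages in weeks; returns \eqn{\mu(age_{hi}) -
#'   \mu(age_{lo})} per draw.
#' @return Numeric vector of per-draw contrasts.
#' @export
contrast <- function(fit, age_hi, age_lo) {
  curve_at(fit, age_hi) - curve_at(fit, age_lo)
}

#' Probability of a sign error
#'
#' The posterior probability that a parameter has the opposite sign from its
#' posterior mean: the fraction of draws strictly on the other side of zero.
#' Draws exactly at zero count toward neither side; if the mean is exactly
#' zero the probability is 0.5 by convention.
#'
#' @param scalar_draws Numeric vector of >= 100 posterior draws.
#' @return Probability in [0, 0.5].
#' @export
sign_error_probability <- function(scalar_draws) {
  if (length(scalar_draws) < 100)
    stop("need at least 100 draws for a sign-error probability.")
  m <- mean(scalar_draws)
  if (m == 0) return(0.5)
  if (m > 0) mean(scalar_draws < 0) else mean(scalar_draws > 0)
}

#' Summarise a set of scalar posterior draws
#'
#' Posterior mean, empirical 2.5 and 97.5 percentiles (linear-interpolation
#' quantiles, R type 7), sign-error probability, and a significance flag
#' raised when the sign-error probability is strictly below 0.025 (the
#' one-sided analogue of a two-sided 0.05 level).
#'
#' @param scalar_draws Numeric vector of >= 100 draws.
#' @param label Estimand label for the output row.
#' @return One-row data.frame: \code{label}, \code{mean}, \code{lower},
#'   \code{upper}, \code{pr}, \code{significant}.
#' @export
summarize_draws <- function(scalar_draws, label = "estimand") {
  if (length(scalar_draws) < 100)
    stop("need at least 100 draws to summarise.")
  qs <- stats::quantile(scalar_draws, c(0.025, 0.975), names = FALSE,
                        type = 7)
  pr <- sign_error_probability(scalar_draws)
  data.frame(label = label, mean = mean(scalar_draws),
             lower = qs[1], upper = qs[2], pr = pr,
             significant = pr < 0.025, stringsAsFactors = FALSE)
}

#' Anchored estimand summaries of a fitted growth model
#'
#' The standard reporting set: the mean curve at the anchor ages 32, 36, 40
#' and 44 weeks PMA, the three consecutive changes, and the overall change
#' from 32 to 44 weeks, each with posterior mean, 95% credible bounds and
#' sign-error probability.
#'
#' @param fit A fitted model.
#' @param anchors Anchor ages (weeks).
#' @param contrasts List of \code{c(hi, lo)} age pairs.
#' @return data.frame with one row per estimand (anchors first, then
#'   contrasts).
#' @export
estimand_summaries <- function(fit, anchors = c(32, 36, 40, 44),
                               contrasts = list(c(36, 32), c(40, 36),
                                                c(44, 40), c(44, 32))) {
  rows <- lapply(anchors, function(a)
    summarize_draws(curve_at(fit, a), sprintf("PMA = %g", a)))
  rows <- c(rows, lapply(contrasts, function(p)
    summarize_draws(contrast(fit, p[1], p[2]),
                    sprintf("(PMA = %g)-(PMA = %g)", p[1], p[2]))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summary of the covariate effect
#'
#' Summary of the linear association \eqn{\gamma} between the standardized
#' subject-level covariate (e.g. the maternal mental-health PC1) and the
#' connectivity measure.
#'
#' @param fit A model fitted with a \code{covariate}.
#' @return One-row summary data.frame (see \code{\link{summarize_draws}}).
#' @export
covariate_effect <- function(fit) {
  M <- pooled_draws(fit)
  if (!"gamma" %in% colnames(M))
    stop("model was fitted without a covariate.")
  summarize_draws(M[, "gamma"], "covariate (per SD)")
}

#' Compare the growth of two connectivity measures
#'
#' Builds the per-scan difference \code{name_a - name_b} (see
#' \code{\link{difference_measure}}), fits the full growth model to the
#' difference, and summarises the standard anchored estimand set. A
#' significant overall contrast indicates the two measures' trajectories
#' change at different rates.
#'
#' @param table Long measure table containing both measures.
#' @param name_a,name_b Measure names.
#' @param ... Passed to \code{\link{pspline_growth}} (sampler settings,
#'   seed, ...).
#' @return List with the fitted \code{fit} and its \code{summaries} (8
#'   rows).
#' @export
compare_measures <- function(table, name_a, name_b, ...) {
  d <- difference_measure(table, name_a, name_b)
  fit <- pspline_growth(value ~ pma_weeks, d, ...)
  list(fit = fit, summaries = estimand_summaries(fit))
}
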