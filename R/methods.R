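# S3 methods for fitted growth models.

#' @export
print.pspline_growth <- function(x, ...) {
  cat("Bayesian penalized B-spline growth model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d observations, %d subjects, %d cohort(s); reference: %s\n",
              nrow(x$data), length(x$subjects), length(x$cohorts),
              x$reference))
  s <- x$settings
  cat(sprintf("Sampler: %d chain(s) x (%d warmup + %d retained, thin %d)\n",
              s$chains, s$warmup, s$iter, s$thin))
  cat(sprintf("Diagnostics: max split R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.pspline_growth <- function(object, ...) {
  colMeans(pooled_draws(object))
}

#' Summarise a fitted growth model
#'
#' Produces the anchored estimand table (anchor means and age contrasts,
#' with 95% credible bounds and sign-error probabilities) plus the cohort,
#' variance and covariate parameter means.
#'
#' @param object A fitted model.
#' @param anchors,contrasts Passed to \code{\link{estimand_summaries}}.
#' @param ... Unused.
#' @return Object of class \code{"summary.pspline_growth"}.
#' @export
summary.pspline_growth <- function(object, anchors = c(32, 36, 40, 44),
                                   contrasts = list(c(36, 32), c(40, 36),
                                                    c(44, 40), c(44, 32)),
                                   ...) {
  est <- estimand_summaries(object, anchors, contrasts)
  M <- pooled_draws(object)
  other <- colMeans(M[, !grepl("^beta\\[", colnames(M)), drop = FALSE])
  cov_row <- if ("gamma" %in% colnames(M)) covariate_effect(object) else NULL
  structure(list(estimands = est, parameters = other, covariate = cov_row,
                 diagnostics = object$diagnostics,
                 n = nrow(object$data), n_subjects = length(object$subjects)),
            class = "summary.pspline_growth")
}

#' @export
print.summary.pspline_growth <- function(x, digits = 3, ...) {
  cat(sprintf("Anchored posterior summaries (%d scans, %d subjects)\n",
              x$n, x$n_subjects))
  tab <- x$estimands
  tab[c("mean", "lower", "upper", "pr")] <-
    lapply(tab[c("mean", "lower", "upper", "pr")], round, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$covariate)) {
    cat("\nCovariate effect (per SD of the composite):\n")
    cv <- x$covariate
    cv[c("mean", "lower", "upper", "pr")] <-
      lapply(cv[c("mean", "lower", "upper", "pr")], round, digits)
    print(cv, row.names = FALSE)
  }
  cat("\nOther parameters (posterior means):\n")
  print(round(x$parameters, digits))
  invisible(x)
}

#' Posterior mean curve and credible band
#'
#' @param object A fitted model.
#' @param ages Ages (weeks) at which to evaluate the reference-cohort mean
#'   curve.
#' @param level Credible level for the band.
#' @param ... Unused.
#' @return data.frame with \code{age}, \code{mean}, \code{lower},
#'   \code{upper}.
#' @export
predict.pspline_growth <- function(object,
                                   ages = seq(min(object$basis$knots),
                                              max(object$basis$knots),
                                              by = 0.25),
                                   level = 0.95, ...) {
  Bd <- beta_draws(object)
  Bm <- build_basis(ages, object$basis)
  curves <- Bd %*% t(Bm)
  al <- (1 - level) / 2
  data.frame(age = ages, mean = colMeans(curves),
             lower = apply(curves, 2, stats::quantile, al),
             upper = apply(curves, 2, stats::quantile, 1 - al))
}

#' @export
fitted.pspline_growth <- function(object, ...) {
  d <- object$data
  M <- pooled_draws(object)
  beta <- colMeans(beta_draws(object))
  mu <- drop(build_basis(d$pma_weeks, object$basis) %*% beta)
  dn <- paste0("delta[", d$cohort, "]")
  dn_ok <- dn %in% colnames(M)
  mu <- mu + ifelse(dn_ok, colMeans(M)[dn], 0)
  si <- match(d$subject_id, object$subjects)
  mu <- mu + object$ranef[si, "intercept"] +
    object$ranef[si, "slope"] * (d$pma_weeks - object$t0)
  if ("gamma" %in% colnames(M) && !is.null(object$covariate))
    mu <- mu + mean(M[, "gamma"]) * object$covariate[si]
  mu
}

#' @export
residuals.pspline_growth <- function(object, ...) {
  object$data$value - fitted(object)
}

#' Posterior predictive simulation from a fitted growth model
#'
#' Draws complete replicate data sets: for each simulation a posterior draw
#' of (curve, offsets, variance components) is selected, new subject random
#' effects and residuals are generated, and a new \code{value} column is
#' produced at the observed design (same subjects, cohorts and ages).
#'
#' @param object A fitted model.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of data.frames shaped like \code{object$data}.
#' @export
simulate.pspline_growth <- function(object, nsim = 1, seed = 1, ...) {
  M <- pooled_draws(object)
  d <- object$data
  B <- build_basis(d$pma_weeks, object$basis)
  si <- match(d$subject_id, object$subjects)
  S <- length(object$subjects)
  with_seed(seed, {
    idx <- sample.int(nrow(M), nsim, replace = nsim > nrow(M))
    lapply(idx, function(i) {
      th <- M[i, ]
      beta <- th[grep("^beta\\[", names(th))]
      mu <- drop(B %*% beta)
      dn <- paste0("delta[", d$cohort, "]")
      mu <- mu + ifelse(dn %in% names(th), th[dn], 0)
      if (object$settings$random_effects) {
        a <- rnorm(S, 0, th["sigma_a"]); b <- rnorm(S, 0, th["sigma_b"])
        mu <- mu + a[si] + b[si] * (d$pma_weeks - object$t0)
      }
      if ("gamma" %in% names(th) && !is.null(object$covariate))
        mu <- mu + th["gamma"] * object$covariate[si]
      out <- d
      out$value <- rnorm(nrow(d), mu,
                         th[paste0("sigma[", d$cohort, "]")])
      out
    })
  })
}

#' Plot a fitted growth trajectory
#'
#' Draws the per-subject longitudinal observations (connected within
#' subject), the posterior mean curve with its 95% credible band, and red
#' bars marking the anchored estimates with their credible intervals.
#'
#' @param x A fitted model.
#' @param anchors Anchor ages to mark.
#' @param main Title.
#' @param ... Passed to \code{plot}.
#' @export
plot.pspline_growth <- function(x, anchors = c(32, 36, 40, 44),
                                main = "Connectivity growth trajectory",
                                ...) {
  d <- x$data
  pr <- predict(x)
  ylim <- range(d$value, pr$lower, pr$upper)
  graphics::plot(d$pma_weeks, d$value, pch = 16, cex = 0.6,
                 col = "grey55", xlab = "Postmenstrual age (weeks)",
                 ylab = "Connectivity strength (Fisher z)",
                 ylim = ylim, main = main, ...)
  for (s in split(d, d$subject_id)) if (nrow(s) > 1) {
    s <- s[order(s$pma_weeks), ]
    graphics::lines(s$pma_weeks, s$value, col = "grey80")
  }
  graphics::polygon(c(pr$age, rev(pr$age)), c(pr$lower, rev(pr$upper)),
                    col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::lines(pr$age, pr$mean, col = "red3", lwd = 2)
  for (a in anchors) {
    s <- summarize_draws(curve_at(x, a), "a")
    graphics::segments(a, s$lower, a, s$upper, col = "red3", lwd = 3)
    graphics::points(a, s$mean, pch = 15, col = "red3")
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
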