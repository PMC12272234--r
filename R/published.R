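#' Reference anchored growth-table estimates
#'
#' Anchored posterior summaries for the six intra- and internetwork
#' connectivity strengths (DMN, FPN, SN and their pairings) reported by a
#' published study of network development from 30 to 44 weeks PMA in 84
#' fetuses and neonates. Each measure carries eight estimands: the mean curve
#' at the anchor ages 32, 36, 40 and 44 weeks, the three consecutive changes,
#' and the overall 32-to-44-week change, with posterior mean, 95% credible
#' bounds, and sign-error probability.
#'
#' These values serve two purposes in this package: they are the default
#' anchor presets for the synthetic-data generator (so simulated trajectories
#' look like real developmental curves), and they support arithmetic
#' consistency checks — by linearity, the overall change must equal the
#' difference of the anchor means at 44 and 32 weeks.
#'
#' @return A data.frame with columns \code{measure}, \code{quantity}
#'   (\code{"PMA32"}, \code{"PMA36"}, \code{"PMA40"}, \code{"PMA44"},
#'   \code{"d36_32"}, \code{"d40_36"}, \code{"d44_40"}, \code{"d44_32"}),
#'   \code{mean}, \code{lower}, \code{upper}, \code{pr}.
#' @examples
#' tab <- reference_growth_tables()
#' subset(tab, measure == "intra_SN" & quantity == "PMA44")$mean  # 0.283
#' @export
reference_growth_tables <- function() {
  q <- c("PMA32", "PMA36", "PMA40", "PMA44",
         "d36_32", "d40_36", "d44_40", "d44_32")
  tab <- function(measure, mean, lower, upper, pr)
    data.frame(measure = measure, quantity = q, mean = mean,
               lower = lower, upper = upper, pr = pr)
  rbind(
    tab("intra_DMN",
        c(-0.059, -0.015, 0.057, 0.140, 0.043, 0.073, 0.083, 0.199),
        c(-0.095, -0.051, 0.014, 0.113, -0.005, 0.034, 0.042, 0.155),
        c(-0.021, 0.017, 0.095, 0.170, 0.079, 0.119, 0.138, 0.245),
        c(0.002, 0.192, 0.008, 0.000, 0.036, 0.002, 0.001, 0.000)),
    tab("intra_FPN",
        c(-0.037, -0.028, 0.133, 0.264, 0.009, 0.161, 0.131, 0.300),
        c(-0.091, -0.074, 0.062, 0.225, -0.053, 0.082, 0.039, 0.240),
        c(0.014, 0.017, 0.210, 0.303, 0.071, 0.252, 0.217, 0.365),
        c(0.077, 0.110, 0.001, 0.000, 0.391, 0.000, 0.005, 0.000)),
    tab("intra_SN",
        c(-0.006, 0.001, 0.163, 0.283, 0.007, 0.161, 0.121, 0.289),
        c(-0.072, -0.060, 0.059, 0.233, -0.081, 0.027, 0.001, 0.196),
        c(0.070, 0.069, 0.264, 0.331, 0.094, 0.284, 0.236, 0.370),
        c(0.418, 0.495, 0.002, 0.000, 0.430, 0.012, 0.024, 0.000)),
    tab("inter_DMN_FPN",
        c(0.024, 0.053, 0.095, 0.161, 0.029, 0.042, 0.066, 0.136),
        c(-0.001, 0.029, 0.053, 0.141, -0.003, -0.001, 0.034, 0.106),
        c(0.050, 0.076, 0.124, 0.183, 0.056, 0.073, 0.119, 0.169),
        c(0.031, 0.000, 0.000, 0.000, 0.037, 0.027, 0.000, 0.000)),
    tab("inter_DMN_SN",
        c(-0.016, -0.030, -0.050, -0.056, -0.014, -0.020, -0.006, -0.040),
        c(-0.036, -0.048, -0.083, -0.072, -0.037, -0.057, -0.028, -0.065),
        c(0.004, -0.011, -0.029, -0.038, 0.010, 0.000, 0.035, -0.013),
        c(0.061, 0.002, 0.000, 0.000, 0.088, 0.025, 0.246, 0.004)),
    tab("inter_FPN_SN",
        c(-0.004, -0.022, -0.033, -0.062, -0.018, -0.011, -0.028, -0.057),
        c(-0.033, -0.045, -0.059, -0.084, -0.046, -0.037, -0.079, -0.093),
        c(0.024, 0.000, 0.008, -0.040, 0.012, 0.037, -0.000, -0.022),
        c(0.376, 0.027, 0.043, 0.000, 0.098, 0.183, 0.023, 0.001))
  )
}

#' Reference anchor means for one measure
#'
#' Convenience accessor for the anchored posterior means at 32, 36, 40 and 44
#' weeks for one of the six connectivity measures, in a form directly usable
#' as \code{\link{true_trajectory}} anchors.
#'
#' @param measure One of the six measure names.
#' @return Named numeric vector of length 4 (names are the anchor ages).
#' @export
reference_anchors <- function(measure = c("intra_DMN", "intra_FPN", "intra_SN",
                                          "inter_DMN_FPN", "inter_DMN_SN",
                                          "inter_FPN_SN")) {
  measure <- match.arg(measure)
  tab <- reference_growth_tables()
  rows <- tab[tab$measure == measure &
                tab$quantity %in% c("PMA32", "PMA36", "PMA40", "PMA44"), ]
  stats::setNames(rows$mean, c(32, 36, 40, 44))
}

#' Pooled sample demographics across the three cohorts
#'
#' Pools per-cohort sample characteristics (counts, birth weight, PMA at
#' birth, sex) into whole-sample summaries by sample-size weighting, and
#' computes the pre-pandemic enrolment fraction of the longitudinal cohort.
#' By default the bundled three-cohort characteristics table is used.
#'
#' @param characteristics A data.frame like the bundled
#'   \code{cohort_characteristics.csv} (one row per cohort with columns
#'   \code{n}, \code{n_female}, \code{birth_weight_mean_g},
#'   \code{pma_birth_mean_wks}, \code{n_prepandemic}), or a path to such a
#'   CSV. Defaults to the bundled table.
#' @return A list with \code{n_total}, \code{mean_birth_weight_g},
#'   \code{mean_pma_birth_wks}, \code{percent_female}, and
#'   \code{prepandemic_percent} (of the cohort reporting it).
#' @examples
#' pooled_demographics()$mean_birth_weight_g  # ~3536 g
#' @export
pooled_demographics <- function(characteristics = NULL) {
  ch <- load_characteristics(characteristics)
  n <- ch$n
  out <- list(
    n_total = sum(n),
    mean_birth_weight_g = sum(n * ch$birth_weight_mean_g) / sum(n),
    mean_pma_birth_wks = sum(n * ch$pma_birth_mean_wks) / sum(n),
    n_female = sum(ch$n_female),
    percent_female = 100 * sum(ch$n_female) / sum(n)
  )
  pre <- !is.na(ch$n_prepandemic)
  if (any(pre))
    out$prepandemic_percent <- 100 * sum(ch$n_prepandemic[pre]) /
      sum(ch$n[pre])
  out
}

load_characteristics <- function(characteristics = NULL) {
  if (is.null(characteristics))
    characteristics <- system.file("extdata", "cohort_characteristics.csv",
                                   package = "fcgrowth", mustWork = TRUE)
  ch <- if (is.character(characteristics))
    utils::read.csv(characteristics, stringsAsFactors = FALSE)
  else as.data.frame(characteristics)
  need <- c("cohort", "n", "n_female", "birth_weight_mean_g",
            "pma_birth_mean_wks")
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("characteristics table lacks columns: ", paste(miss, collapse = ", "))
  ch
}
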