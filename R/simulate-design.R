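#' Cohort design for the synthetic study generator
#'
#' Describes one cohort of the emulated study: how many subjects it enrols,
#' the scheduled scan visits (mean and SD of PMA at each visit, in weeks),
#' and the probability that any scheduled visit is missing.
#'
#' @param cohort_name One of \code{"fetal_neonatal"}, \code{"neonatal"},
#'   \code{"dhcp"}.
#' @param n_subjects Number of subjects (> 0).
#' @param visit_schedule List of \code{c(mean, sd)} pairs, one per visit;
#'   visit means must lie in [28, 48] weeks PMA.
#' @param missingness_rate Probability in [0, 1) that a scheduled visit is
#'   absent.
#' @return An object of class \code{"cohort_design"}.
#' @export
cohort_design <- function(cohort_name = c("fetal_neonatal", "neonatal", "dhcp"),
                          n_subjects, visit_schedule, missingness_rate = 0) {
  cohort_name <- match.arg(cohort_name)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects <= 0)
    stop("`n_subjects` must be a positive integer.")
  if (!is.list(visit_schedule)) visit_schedule <- list(visit_schedule)
  sched <- lapply(visit_schedule, function(v) {
    v <- as.numeric(v)
    if (length(v) != 2 || v[2] < 0) stop("each visit must be c(mean, sd).")
    if (v[1] < 28 || v[1] > 48)
      stop("visit mean PMA must be within [28, 48] weeks.")
    v
  })
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("`missingness_rate` must be in [0, 1).")
  structure(list(cohort_name = cohort_name, n_subjects = n_subjects,
                 visit_schedule = sched,
                 missingness_rate = missingness_rate),
            class = "cohort_design")
}

#' Default three-cohort study design
#'
#' The study conditions the generator emulates: 29 longitudinal
#' fetal-neonatal subjects scanned around 31.2, 35.3 and 43.4 weeks PMA; 31
#' cross-sectional neonates around 44.4 weeks; and 24 dHCP-style neonates
#' around 40.2 weeks (visit means and SDs taken from the bundled cohort
#' characteristics table).
#'
#' @param characteristics Optional alternative characteristics table or path;
#'   see \code{\link{pooled_demographics}}.
#' @return List of three \code{\link{cohort_design}} objects.
#' @export
study_design <- function(characteristics = NULL) {
  ch <- load_characteristics(characteristics)
  lapply(seq_len(nrow(ch)), function(i) {
    mu <- as.numeric(strsplit(as.character(ch$scan_pma_means[i]), ";")[[1]])
    sd <- as.numeric(strsplit(as.character(ch$scan_pma_sds[i]), ";")[[1]])
    cohort_design(ch$cohort[i], ch$n[i],
                  Map(c, mu, sd), missingness_rate = 0)
  })
}

#' Simulate the visit table of a multi-cohort longitudinal design
#'
#' Draws a PMA-at-scan for every scheduled visit of every subject from the
#' design's normal visit distributions, truncated to [28, 48] weeks by
#' resampling. Scheduled visits are independently dropped with the design's
#' missingness rate; subjects left with no visits are removed from the
#' output. Longitudinal subjects keep a stable \code{subject_id} across
#' visits.
#'
#' @param designs A \code{\link{cohort_design}} or list of them.
#' @param seed Integer seed; the function does not touch global RNG state.
#' @return data.frame with columns \code{subject_id}, \code{cohort},
#'   \code{visit}, \code{pma_weeks}.
#' @examples
#' d <- simulate_design(study_design(), seed = 7)
#' nrow(d)  # 142 scans: 29 x 3 + 31 + 24
#' @export
simulate_design <- function(designs, seed) {
  if (inherits(designs, "cohort_design")) designs <- list(designs)
  if (!length(designs))
    stop("`designs` is empty: provide at least one cohort_design.")
  if (!all(vapply(designs, inherits, TRUE, "cohort_design")))
    stop("`designs` must be cohort_design objects.")
  with_seed(seed, {
    out <- lapply(designs, function(d) {
      nv <- length(d$visit_schedule)
      rows <- do.call(rbind, lapply(seq_len(nv), function(v) {
        mv <- d$visit_schedule[[v]]
        data.frame(
          subject_id = sprintf("%s_%02d", abbreviate_cohort(d$cohort_name),
                               seq_len(d$n_subjects)),
          cohort = d$cohort_name,
          visit = v,
          pma_weeks = rnorm_trunc(d$n_subjects, mv[1], mv[2], 28, 48),
          stringsAsFactors = FALSE)
      }))
      if (d$missingness_rate > 0)
        rows <- rows[runif(nrow(rows)) >= d$missingness_rate, , drop = FALSE]
      rows
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

abbreviate_cohort <- function(x) {
  c(fetal_neonatal = "fet", neonatal = "neo", dhcp = "dhcp")[[x]]
}

#' True growth trajectory and noise structure for the generator
#'
#' Specifies the generative analogue of the growth model: a smooth mean
#' trajectory through anchor (age, value) pairs in Fisher-z units, subject
#' random-intercept and random-slope SDs, per-cohort additive offsets (the
#' reference cohort must have offset exactly 0) and per-cohort residual SDs.
#' Between anchors the mean is interpolated with a shape-preserving monotone
#' cubic (Fritsch-Carlson) by default, so synthetic truths are smooth without
#' invented wiggles; outside the anchor span the curve is held constant.
#'
#' @param anchor_ages Strictly increasing PMA weeks.
#' @param anchor_values Fisher-z values at the anchors.
#' @param interpolation \code{"monotone_cubic"} (default) or \code{"linear"}.
#' @param sigma_a Random-intercept SD (Fisher-z), >= 0.
#' @param sigma_b Random-slope SD (Fisher-z per week), >= 0.
#' @param cohort_offsets Named additive shifts per cohort; the reference
#'   (first) entry must be exactly 0.
#' @param cohort_sigmas Named residual SDs per cohort, >= 0.
#' @param t0 Centering age for the random slope, weeks.
#' @return Object of class \code{"true_trajectory"} with an \code{f_true}
#'   function.
#' @export
true_trajectory <- function(anchor_ages, anchor_values,
                            interpolation = c("monotone_cubic", "linear"),
                            sigma_a = 0.05, sigma_b = 0.01,
                            cohort_offsets = c(fetal_neonatal = 0,
                                               neonatal = 0.02,
                                               dhcp = -0.02),
                            cohort_sigmas = c(fetal_neonatal = 0.10,
                                              neonatal = 0.08,
                                              dhcp = 0.08),
                            t0 = 37) {
  interpolation <- match.arg(interpolation)
  anchor_ages <- as.numeric(anchor_ages)
  anchor_values <- as.numeric(anchor_values)
  if (length(anchor_ages) != length(anchor_values) || length(anchor_ages) < 2)
    stop("anchors must give >= 2 (age, value) pairs.")
  if (any(diff(anchor_ages) <= 0))
    stop("`anchor_ages` must be strictly increasing.")
  if (sigma_a < 0 || sigma_b < 0 || any(cohort_sigmas < 0))
    stop("all SDs must be >= 0.")
  if (is.null(names(cohort_offsets)) || is.null(names(cohort_sigmas)))
    stop("`cohort_offsets` and `cohort_sigmas` must be named by cohort.")
  if (abs(cohort_offsets[[1]]) != 0)
    stop("the reference (first) cohort offset must be exactly 0.")
  lo <- min(anchor_ages); hi <- max(anchor_ages)
  base <- if (interpolation == "monotone_cubic")
    stats::splinefun(anchor_ages, anchor_values, method = "monoH.FC")
  else stats::approxfun(anchor_ages, anchor_values, rule = 2)
  f_true <- function(age) base(pmin(pmax(age, lo), hi))
  structure(list(anchor_ages = anchor_ages, anchor_values = anchor_values,
                 interpolation = interpolation, f_true = f_true,
                 sigma_a = sigma_a, sigma_b = sigma_b,
                 cohort_offsets = cohort_offsets,
                 cohort_sigmas = cohort_sigmas, t0 = t0),
            class = "true_trajectory")
}

#' Simulate per-scan connectivity-strength observations
#'
#' Generates one Fisher-z observation per design row under the hierarchical
#' growth structure the model assumes:
#' \deqn{y = f_{true}(t) + \delta_{cohort} + a_i + b_i (t - t_0) + \epsilon,}
#' with subject effects \eqn{a_i \sim N(0, \sigma_a^2)},
#' \eqn{b_i \sim N(0, \sigma_b^2)} constant within subject and residuals
#' \eqn{\epsilon \sim N(0, \sigma_{cohort}^2)}.
#'
#' @param design_table Output of \code{\link{simulate_design}}.
#' @param traj A \code{\link{true_trajectory}} covering every cohort present.
#' @param seed Integer seed.
#' @param measure Measure name stored in the output rows.
#' @return data.frame with columns \code{subject_id}, \code{cohort},
#'   \code{visit}, \code{pma_weeks}, \code{measure}, \code{value}.
#' @export
simulate_measures <- function(design_table, traj, seed,
                              measure = "intra_SN") {
  if (!inherits(traj, "true_trajectory"))
    stop("`traj` must be a true_trajectory.")
  need <- c("subject_id", "cohort", "pma_weeks")
  if (!all(need %in% names(design_table)))
    stop("`design_table` must have columns subject_id, cohort, pma_weeks.")
  cohorts <- unique(design_table$cohort)
  miss <- setdiff(cohorts, names(traj$cohort_offsets))
  miss2 <- setdiff(cohorts, names(traj$cohort_sigmas))
  if (length(miss) || length(miss2))
    stop("no offset/sigma for cohort(s): ",
         paste(unique(c(miss, miss2)), collapse = ", "))
  with_seed(seed, {
    subj <- unique(design_table$subject_id)
    a <- stats::setNames(rnorm(length(subj), 0, traj$sigma_a), subj)
    b <- stats::setNames(rnorm(length(subj), 0, traj$sigma_b), subj)
    t <- design_table$pma_weeks
    eps <- rnorm(nrow(design_table)) *
      traj$cohort_sigmas[design_table$cohort]
    value <- traj$f_true(t) + traj$cohort_offsets[design_table$cohort] +
      a[design_table$subject_id] + b[design_table$subject_id] * (t - traj$t0) +
      eps
    out <- design_table[, intersect(c("subject_id", "cohort", "visit",
                                      "pma_weeks"), names(design_table))]
    out$measure <- measure
    out$value <- as.numeric(value)
    rownames(out) <- NULL
    out
  })
}
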