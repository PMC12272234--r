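#' Simulate node time series with a target correlation structure
#'
#' Draws \code{n_frames} i.i.d. multivariate-normal frames whose population
#' node-by-node correlation equals \code{target_corr}. Empirical correlations
#' converge to the target as the number of frames grows.
#'
#' @param n_frames Number of frames (>= nodes + 2).
#' @param target_corr Symmetric positive semi-definite matrix with unit
#'   diagonal; column names, if present, label the nodes.
#' @param seed Integer seed.
#' @return Numeric matrix, frames by nodes.
#' @export
simulate_timeseries <- function(n_frames, target_corr, seed) {
  target_corr <- as.matrix(target_corr)
  p <- ncol(target_corr)
  if (nrow(target_corr) != p) stop("`target_corr` must be square.")
  if (max(abs(target_corr - t(target_corr))) > 1e-8)
    stop("`target_corr` must be symmetric.")
  if (max(abs(diag(target_corr) - 1)) > 1e-8)
    stop("`target_corr` must have unit diagonal.")
  ev <- eigen(target_corr, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ev$values))
  if (min(ev$values) < -tol)
    stop(sprintf(paste0("`target_corr` is not positive semi-definite ",
                        "(smallest eigenvalue %.6g)."), min(ev$values)))
  if (n_frames < p + 2) stop("`n_frames` must be at least nodes + 2.")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  with_seed(seed, {
    X <- matrix(rnorm(n_frames * p), n_frames, p) %*% t(L)
    colnames(X) <- colnames(target_corr)
    X
  })
}

#' Simulate per-frame quality-control metrics and per-run motion summaries
#'
#' Emulates the scalar QC stream of a multi-run scan: per-frame
#' signal-to-noise ratio, registration quality, and frame-to-frame motion,
#' plus one mean frame-to-frame displacement (FFD, mm) per run. A fraction
#' \code{outlier_rate} of frames is planted as outliers with strongly
#' inflated motion and deflated SNR, so the downstream 1-SD censoring rule
#' catches them.
#'
#' @param n_runs Number of runs.
#' @param frames_per_run Frames per run.
#' @param outlier_rate Planted outlier fraction in [0, 1).
#' @param seed Integer seed.
#' @param ffd_means Optional numeric vector (length \code{n_runs}) of mean
#'   FFD values to plant; by default drawn around 0.12 mm.
#' @return List with \code{frames} (data.frame: run, frame, snr,
#'   reg_quality, motion, planted_outlier) and \code{runs} (data.frame: run,
#'   mean_ffd).
#' @export
simulate_qc <- function(n_runs, frames_per_run, outlier_rate = 0.05, seed,
                        ffd_means = NULL) {
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("`outlier_rate` must be in [0, 1).")
  with_seed(seed, {
    n <- n_runs * frames_per_run
    snr <- rnorm(n, 100, 2)
    reg <- rnorm(n, 0.95, 0.01)
    mot <- abs(rnorm(n, 0.05, 0.01))
    out <- runif(n) < outlier_rate
    snr[out] <- rnorm(sum(out), 70, 5)
    mot[out] <- abs(rnorm(sum(out), 0.5, 0.05))
    frames <- data.frame(run = rep(seq_len(n_runs), each = frames_per_run),
                         frame = rep(seq_len(frames_per_run), n_runs),
                         snr = snr, reg_quality = reg, motion = mot,
                         planted_outlier = out)
    ffd <- ffd_means %||% rnorm_trunc(n_runs, 0.12, 0.04, 0.01, Inf)
    if (length(ffd) != n_runs) stop("`ffd_means` must have one value per run.")
    list(frames = frames, runs = data.frame(run = seq_len(n_runs),
                                            mean_ffd = as.numeric(ffd)))
  })
}

#' Build a node correlation target from network-level strengths
#'
#' Inverts the summary direction of the pipeline: given Fisher-z strengths
#' for the six intra/internetwork measures, constructs a node-by-node
#' correlation matrix in which every within-network pair carries
#' \code{tanh(z_intra)} and every cross-network pair \code{tanh(z_inter)}.
#' The matrix is projected to the nearest positive semi-definite correlation
#' matrix (eigenvalue clipping plus diagonal rescaling), so realized
#' pairwise correlations can differ very slightly from the inputs when the
#' block pattern is not exactly feasible.
#'
#' @param strengths Named numeric vector with entries \code{intra_DMN},
#'   \code{intra_FPN}, \code{intra_SN}, \code{inter_DMN_FPN},
#'   \code{inter_DMN_SN}, \code{inter_FPN_SN} (Fisher-z).
#' @param networks Network specification list, see \code{\link{default_networks}}.
#' @return Correlation matrix over all network nodes.
#' @export
target_corr_from_strengths <- function(strengths,
                                       networks = default_networks()) {
  need <- c("intra_DMN", "intra_FPN", "intra_SN",
            "inter_DMN_FPN", "inter_DMN_SN", "inter_FPN_SN")
  if (!all(need %in% names(strengths)))
    stop("`strengths` must name all six measures.")
  nodes <- unlist(lapply(networks, `[[`, "nodes"), use.names = FALSE)
  p <- length(nodes)
  R <- diag(p); dimnames(R) <- list(nodes, nodes)
  member <- rep(names(networks), vapply(networks, function(s)
    length(s$nodes), 1L))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    a <- member[i]; b <- member[j]
    key <- if (a == b) paste0("intra_", a)
    else paste0("inter_", paste(sort(c(a, b)), collapse = "_"))
    R[i, j] <- R[j, i] <- tanh(strengths[[key]])
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    v <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(v, p) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    dimnames(R) <- list(nodes, nodes)
  }
  R
}

#' Simulate a full set of scans with node time series and QC
#'
#' For every row of a design table, builds the node correlation target from
#' the six true trajectories evaluated at that scan's PMA (plus the scan's
#' cohort offset and subject effects on each measure), then simulates
#' multi-run node time series and QC metrics. The result feeds the
#' connectivity pipeline end to end.
#'
#' @param design_table Output of \code{\link{simulate_design}}.
#' @param trajectories Named list of six \code{\link{true_trajectory}}
#'   objects, one per measure.
#' @param seed Integer seed.
#' @param n_runs,frames_per_run,tr_seconds Acquisition layout of each scan.
#' @param outlier_rate Planted QC outlier fraction.
#' @param networks Network specification.
#' @return List of scan records (subject_id, cohort, pma_weeks, runs).
#' @export
simulate_scans <- function(design_table, trajectories, seed,
                           n_runs = 3, frames_per_run = 150,
                           tr_seconds = 1.95, outlier_rate = 0.03,
                           networks = default_networks()) {
  need <- c("intra_DMN", "intra_FPN", "intra_SN",
            "inter_DMN_FPN", "inter_DMN_SN", "inter_FPN_SN")
  if (!all(need %in% names(trajectories)))
    stop("`trajectories` must name all six measures.")
  seeds <- derive_seeds(seed, 2L * nrow(design_table))
  lapply(seq_len(nrow(design_table)), function(i) {
    row <- design_table[i, ]
    z <- vapply(need, function(m) {
      tr <- trajectories[[m]]
      tr$f_true(row$pma_weeks) + tr$cohort_offsets[[row$cohort]]
    }, numeric(1))
    R <- target_corr_from_strengths(z, networks)
    series <- simulate_timeseries(n_runs * frames_per_run, R,
                                  seed = seeds[2 * i - 1])
    qc <- simulate_qc(n_runs, frames_per_run, outlier_rate,
                      seed = seeds[2 * i])
    runs <- lapply(seq_len(n_runs), function(r) {
      idx <- ((r - 1) * frames_per_run + 1):(r * frames_per_run)
      list(series = series[idx, , drop = FALSE],
           tr_seconds = tr_seconds,
           qc = qc$frames[qc$frames$run == r,
                          c("snr", "reg_quality", "motion")],
           mean_ffd = qc$runs$mean_ffd[r])
    })
    list(subject_id = row$subject_id, cohort = row$cohort,
         pma_weeks = row$pma_weeks, runs = runs)
  })
}
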