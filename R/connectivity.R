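#' Network specification
#'
#' Names the seed nodes of one cortical network. The three networks of
#' interest are the default mode network (DMN: posterior cingulate, medial
#' prefrontal cortex, bilateral angular gyri), the frontoparietal network
#' (FPN: bilateral dorsolateral prefrontal cortex and intraparietal sulci),
#' and the salience network (SN: dorsal anterior cingulate and bilateral
#' anterior insulae).
#'
#' @param name \code{"DMN"}, \code{"FPN"} or \code{"SN"}.
#' @param nodes Character vector of node labels (4 for DMN/FPN, 3 for SN).
#' @return Object of class \code{"network_spec"}.
#' @export
network_spec <- function(name = c("DMN", "FPN", "SN"), nodes) {
  name <- match.arg(name)
  nodes <- as.character(nodes)
  expected <- c(DMN = 4L, FPN = 4L, SN = 3L)[[name]]
  if (length(nodes) != expected)
    stop(sprintf("%s must have %d nodes.", name, expected))
  if (anyDuplicated(nodes)) stop("node labels must be unique.")
  structure(list(name = name, nodes = nodes), class = "network_spec")
}

#' Default DMN/FPN/SN node sets
#'
#' @return Named list of three \code{\link{network_spec}} objects whose node
#'   labels are unique across networks (11 nodes in total).
#' @export
default_networks <- function() {
  list(
    DMN = network_spec("DMN", c("PCC", "mPFC", "rAngular", "lAngular")),
    FPN = network_spec("FPN", c("rdlPFC", "ldlPFC", "lIPS", "rIPS")),
    SN = network_spec("SN", c("dACC", "lAntInsula", "rAntInsula")))
}

#' Censor outlying frames by pooled quality-control thresholds
#'
#' A frame is kept iff its SNR and registration quality are no more than one
#' standard deviation below, and its motion no more than one standard
#' deviation above, the mean of that metric pooled over all of the
#' subject's runs. Comparisons are non-strict, so frames exactly at a
#' threshold (and all frames, when a metric is constant) are kept.
#'
#' @param qc data.frame with columns \code{snr}, \code{reg_quality},
#'   \code{motion}, one row per frame, pooled over all runs of the scan.
#' @return Logical keep-mask over frames. Errors if every frame would be
#'   censored (the scan should be dropped) or if any metric is non-finite.
#' @export
censor_frames <- function(qc) {
  need <- c("snr", "reg_quality", "motion")
  if (!all(need %in% names(qc)))
    stop("`qc` must have columns snr, reg_quality, motion.")
  if (nrow(qc) < 2) stop("need at least 2 frames to censor.")
  for (m in need) {
    bad <- which(!is.finite(qc[[m]]))
    if (length(bad))
      stop(sprintf("non-finite %s at frame(s) %s.", m,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  keep <- qc$snr >= mean(qc$snr) - stats::sd(qc$snr) &
    qc$reg_quality >= mean(qc$reg_quality) - stats::sd(qc$reg_quality) &
    qc$motion <= mean(qc$motion) + stats::sd(qc$motion)
  if (!any(keep))
    stop_fcg("all frames censored: drop this scan.", "fcg_unusable_scan")
  keep
}

#' Exclude runs by mean frame-to-frame displacement
#'
#' Runs whose mean frame-to-frame displacement exceeds the threshold
#' (strictly greater than 0.2 mm by default) are removed; a run at exactly
#' the threshold is kept.
#'
#' @param mean_ffd Numeric vector of per-run mean FFD (mm), or a list of run
#'   records each carrying a \code{mean_ffd} element.
#' @param threshold Exclusion threshold in mm.
#' @return Logical keep-mask over runs; errors (class
#'   \code{"fcg_unusable_scan"}) if no run survives.
#' @export
exclude_runs <- function(mean_ffd, threshold = 0.2) {
  if (is.list(mean_ffd))
    mean_ffd <- vapply(mean_ffd, function(r) r$mean_ffd, numeric(1))
  if (any(!is.finite(mean_ffd))) stop("`mean_ffd` must be finite.")
  keep <- mean_ffd <= threshold
  if (!any(keep))
    stop_fcg("all runs exceed the motion threshold: scan unusable.",
             "fcg_unusable_scan")
  keep
}

#' Regress confounds of no interest from node time series
#'
#' Removes nuisance structure (at minimum an intercept plus linear and
#' quadratic drifts; optionally motion parameters and tissue means) by
#' ordinary least squares, returning residuals orthogonal to every confound
#' column.
#'
#' @param series Frames-by-nodes numeric matrix.
#' @param confounds Frames-by-q confound matrix of full column rank with
#'   fewer columns than frames.
#' @return Residual series, same shape as \code{series}.
#' @export
regress_confounds <- function(series, confounds) {
  series <- as.matrix(series); confounds <- as.matrix(confounds)
  if (nrow(series) != nrow(confounds))
    stop("`series` and `confounds` must have the same number of frames.")
  if (ncol(confounds) >= nrow(confounds))
    stop("more confound columns than frames: model is unidentifiable.")
  qrC <- qr(confounds)
  if (qrC$rank < ncol(confounds)) {
    dropped <- qrC$pivot[(qrC$rank + 1):ncol(confounds)]
    nm <- colnames(confounds)[dropped] %||% as.character(dropped)
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(nm, collapse = ", "))
  }
  res <- qr.resid(qrC, series)
  dimnames(res) <- dimnames(series)
  res
}

#' Drift confound matrix
#'
#' Intercept, linear and quadratic drift regressors for a given number of
#' frames (time centered and scaled to [-1, 1] for conditioning).
#'
#' @param n_frames Number of frames.
#' @return n_frames x 3 matrix with columns intercept, linear, quadratic.
#' @export
drift_confounds <- function(n_frames) {
  t <- seq(-1, 1, length.out = n_frames)
  cbind(intercept = 1, linear = t, quadratic = t^2)
}

#' Temporal Gaussian smoothing of node time series
#'
#' Zero-phase convolution of each node's time course with a unit-sum
#' Gaussian kernel. The kernel width is chosen so the filter's magnitude
#' response at \code{cutoff_hz} is one half, i.e. the "cutoff" is the
#' 50%-amplitude frequency; the width is refined against the discrete
#' kernel's actual transfer function, not just the continuous formula.
#' Edges are handled by reflection.
#'
#' @param series Frames-by-nodes matrix (a bare vector is treated as one
#'   node).
#' @param tr_seconds Repetition time (s) between frames, > 0.
#' @param cutoff_hz Half-amplitude frequency (Hz); must be below the Nyquist
#'   frequency \code{1/(2 tr_seconds)}.
#' @return Filtered series, same shape.
#' @export
temporal_smooth <- function(series, tr_seconds, cutoff_hz = 0.12) {
  if (tr_seconds <= 0) stop("`tr_seconds` must be > 0.")
  nyq <- 1 / (2 * tr_seconds)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.3f Hz is not below the Nyquist frequency %.3f Hz.",
                 cutoff_hz, nyq))
  vec_in <- is.null(dim(series))
  X <- as.matrix(series)
  # continuous-time starting point: |H(f)| = exp(-2 pi^2 sigma^2 f^2) = 1/2
  sigma0 <- sqrt(log(2) / 2) / (pi * cutoff_hz) / tr_seconds  # in frames
  omega <- 2 * pi * cutoff_hz * tr_seconds                    # rad / frame
  kernel <- function(sig) {
    r <- max(1L, ceiling(4 * sig))
    w <- exp(-((-r):r)^2 / (2 * sig^2))
    w / sum(w)
  }
  resp <- function(sig) {
    w <- kernel(sig); r <- (length(w) - 1L) / 2L
    sum(w * cos(omega * ((-r):r)))
  }
  # refine sigma so the sampled kernel itself attenuates cutoff_hz to 0.5
  g <- function(s) resp(s) - 0.5
  sig <- if (g(sigma0 / 4) > 0 && g(sigma0 * 4) < 0)
    stats::uniroot(g, c(sigma0 / 4, sigma0 * 4), tol = 1e-6)$root else sigma0
  w <- kernel(sig); r <- (length(w) - 1L) / 2L
  n <- nrow(X)
  if (n < 2) return(series)
  pad <- function(col) {
    ref <- min(r, n - 1L)
    head_ref <- col[(ref + 1L):2L]
    tail_ref <- col[(n - 1L):(n - ref)]
    if (r > ref) { # short series: extend reflection cyclically
      head_ref <- rep(c(col[-1L], rev(col)[-1L]), length.out = r)[r:1]
      tail_ref <- rep(c(rev(col)[-1L], col[-1L]), length.out = r)
    }
    c(head_ref, col, tail_ref)
  }
  out <- apply(X, 2, function(col) {
    p <- pad(col)
    stats::filter(p, w, method = "convolution", sides = 2)[(r + 1L):(r + n)]
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(X))
  if (vec_in) drop(out) else out
}

#' Seed (region-average) time course
#'
#' Per-frame arithmetic mean of the voxel time courses selected by a region
#' mask.
#'
#' @param voxel_series Frames-by-voxels matrix.
#' @param roi_mask Logical or integer index selecting >= 1 voxel column.
#' @return Numeric vector of length frames.
#' @export
seed_timecourse <- function(voxel_series, roi_mask) {
  X <- as.matrix(voxel_series)
  sel <- X[, roi_mask, drop = FALSE]
  if (ncol(sel) < 1) stop("`roi_mask` selects no voxels.")
  rowMeans(sel)
}

#' Fisher-z connectivity matrix from node time series
#'
#' Pearson correlations between every node pair over the retained frames,
#' transformed with Fisher's z (\code{atanh}). The diagonal is undefined and
#' returned as \code{NA}.
#'
#' @param node_series Frames-by-nodes matrix with >= \code{min_frames} rows.
#' @param min_frames Minimum number of frames (default 4).
#' @return Symmetric nodes-by-nodes matrix of z-values with \code{NA}
#'   diagonal.
#' @export
fisher_z_matrix <- function(node_series, min_frames = 4) {
  X <- as.matrix(node_series)
  if (nrow(X) < min_frames)
    stop(sprintf("need at least %d retained frames.", min_frames))
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    nm <- colnames(X)[v == 0] %||% as.character(which(v == 0))
    stop("zero-variance node(s): ", paste(nm, collapse = ", "))
  }
  r <- stats::cor(X)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12))
    stop("perfectly correlated node pair: correlation is degenerate.")
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

# Unordered within-network pairs / all cross-network pairs, as label pairs.
network_pairs <- function(spec_a, spec_b = NULL) {
  if (is.null(spec_b)) {
    n <- spec_a$nodes
    do.call(rbind, lapply(seq_along(n)[-length(n)], function(i)
      cbind(n[i], n[(i + 1):length(n)])))
  } else {
    as.matrix(expand.grid(spec_a$nodes, spec_b$nodes,
                          stringsAsFactors = FALSE))
  }
}

#' Intra- or internetwork connectivity strength
#'
#' Within-network strength is the mean Fisher-z over all unordered node
#' pairs of one network (6 pairs for the 4-node DMN/FPN, 3 for the 3-node
#' SN); between-network strength is the mean over all cross-network pairs
#' (16 for DMN-FPN, 12 for DMN-SN and FPN-SN).
#'
#' @param z_matrix Fisher-z matrix covering all named nodes (rows/columns
#'   labelled by node).
#' @param spec_a A \code{\link{network_spec}}.
#' @param spec_b Optional second network; if supplied the cross-network
#'   strength is returned.
#' @return Single Fisher-z value.
#' @export
network_strength <- function(z_matrix, spec_a, spec_b = NULL) {
  nodes <- unique(c(spec_a$nodes, if (!is.null(spec_b)) spec_b$nodes))
  miss <- setdiff(nodes, rownames(z_matrix) %||% character())
  if (length(miss))
    stop("z_matrix lacks node(s): ", paste(miss, collapse = ", "))
  pr <- network_pairs(spec_a, spec_b)
  mean(z_matrix[cbind(pr[, 1], pr[, 2])])
}

#' Per-scan difference between two connectivity measures
#'
#' Builds \code{value_a - value_b} for every scan at which both measures are
#' present. Scans lacking either measure are omitted and counted in the
#' \code{"omitted"} attribute of the result.
#'
#' @param table Long measure table with columns \code{subject_id},
#'   \code{cohort}, \code{pma_weeks}, \code{measure}, \code{value}.
#' @param name_a,name_b Measure names present in \code{table}.
#' @return Measure-table rows named \code{"diff_<a>_minus_<b>"}.
#' @export
difference_measure <- function(table, name_a, name_b) {
  for (nm in c(name_a, name_b))
    if (!nm %in% table$measure)
      stop(sprintf("unknown measure '%s'.", nm))
  key_cols <- intersect(c("subject_id", "cohort", "visit", "pma_weeks"),
                        names(table))
  a <- table[table$measure == name_a, c(key_cols, "value")]
  b <- table[table$measure == name_b, c(key_cols, "value")]
  m <- merge(a, b, by = key_cols, suffixes = c("_a", "_b"))
  out <- m[key_cols]
  out$measure <- paste0("diff_", name_a, "_minus_", name_b)
  out$value <- m$value_a - m$value_b
  n_scans <- length(unique(do.call(paste, table[key_cols])))
  attr(out, "omitted") <- n_scans - nrow(out)
  rownames(out) <- NULL
  out
}

#' Compute the six connectivity strengths for a set of scans
#'
#' The per-scan pipeline: exclude runs by mean frame-to-frame displacement,
#' censor frames by pooled QC thresholds, optionally regress drift
#' confounds and temporally smooth each retained run, then correlate the
#' retained frames (concatenated across runs by default) and summarise the
#' Fisher-z matrix into the three intra- and three internetwork strengths.
#'
#' @param scans List of scan records as produced by
#'   \code{\link{simulate_scans}}: each has \code{subject_id},
#'   \code{cohort}, \code{pma_weeks}, and \code{runs} (each run a list with
#'   \code{series}, \code{tr_seconds}, \code{qc}, \code{mean_ffd}).
#' @param networks Network specification list.
#' @param min_retained_frames Scans retaining fewer frames are omitted
#'   (permissive floor of 100 by default).
#' @param ffd_threshold Run-exclusion threshold, mm.
#' @param preprocess Apply drift regression and temporal smoothing per run
#'   before correlation.
#' @param per_run Correlate each run separately and average the z-matrices
#'   over runs, instead of correlating concatenated frames.
#' @return Long measure table (six rows per usable scan) with a
#'   \code{"qc_report"} attribute (censored-frame counts, excluded runs,
#'   omitted scans).
#' @export
compute_measure_table <- function(scans, networks = default_networks(),
                                  min_retained_frames = 100,
                                  ffd_threshold = 0.2,
                                  preprocess = TRUE, per_run = FALSE) {
  rows <- list(); omitted <- list()
  n_censored <- 0L; n_frames_total <- 0L; n_runs_excluded <- 0L
  for (scan in scans) {
    res <- tryCatch({
      keep_runs <- exclude_runs(vapply(scan$runs, `[[`, numeric(1),
                                       "mean_ffd"), ffd_threshold)
      n_runs_excluded <- n_runs_excluded + sum(!keep_runs)
      runs <- scan$runs[keep_runs]
      qc <- do.call(rbind, lapply(runs, `[[`, "qc"))
      keep_frames <- censor_frames(qc)
      n_censored <- n_censored + sum(!keep_frames)
      n_frames_total <- n_frames_total + length(keep_frames)
      proc <- list(); off <- 0L
      for (r in runs) {
        nf <- nrow(r$series)
        s <- r$series
        if (preprocess) {
          s <- regress_confounds(s, drift_confounds(nf))
          s <- temporal_smooth(s, r$tr_seconds)
        }
        proc[[length(proc) + 1L]] <- s[keep_frames[(off + 1L):(off + nf)], ,
                                       drop = FALSE]
        off <- off + nf
      }
      if (sum(vapply(proc, nrow, 1L)) < min_retained_frames)
        stop_fcg("too few retained frames.", "fcg_unusable_scan")
      z <- if (per_run) {
        zs <- lapply(proc[vapply(proc, nrow, 1L) >= 4], fisher_z_matrix)
        Reduce(`+`, zs) / length(zs)
      } else fisher_z_matrix(do.call(rbind, proc))
      vals <- c(
        intra_DMN = network_strength(z, networks$DMN),
        intra_FPN = network_strength(z, networks$FPN),
        intra_SN = network_strength(z, networks$SN),
        inter_DMN_FPN = network_strength(z, networks$DMN, networks$FPN),
        inter_DMN_SN = network_strength(z, networks$DMN, networks$SN),
        inter_FPN_SN = network_strength(z, networks$FPN, networks$SN))
      data.frame(subject_id = scan$subject_id, cohort = scan$cohort,
                 pma_weeks = scan$pma_weeks, measure = names(vals),
                 value = as.numeric(vals), stringsAsFactors = FALSE)
    }, fcg_unusable_scan = function(e) e)
    if (inherits(res, "condition"))
      omitted[[length(omitted) + 1L]] <- list(subject_id = scan$subject_id,
                                              pma_weeks = scan$pma_weeks,
                                              reason = conditionMessage(res))
    else rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "qc_report") <- list(
    frames_censored = n_censored, frames_total = n_frames_total,
    runs_excluded = n_runs_excluded, scans_omitted = omitted)
  out
}
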