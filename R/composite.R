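#' Maternal mental-health composite: first principal component
#'
#' Builds the composite index of the four prenatal mental-health instruments
#' (EPDS depression, PSS perceived stress, STAI state and trait anxiety):
#' the four scores are standardized (mean 0, SD 1 with the n-1 denominator),
#' PCA is run on the resulting correlation matrix, and the first principal
#' component is extracted. The loading sign is fixed so the loadings sum to
#' a positive value, making higher composite scores mean more symptoms.
#'
#' @param records data.frame with columns \code{subject_id}, \code{epds}
#'   (0-30), \code{pss} (0-56), \code{stai_state} and \code{stai_trait}
#'   (20-80). At least 5 complete records are required.
#' @param na_action \code{"error"} (default) rejects incomplete records,
#'   listing the subjects; \code{"omit"} drops them and reports the omitted
#'   subjects in the \code{"omitted"} attribute (no imputation either way).
#' @return Object of class \code{"fcg_pc1"}: \code{scores} (named by
#'   subject), \code{loadings} (unit-norm 4-vector), and
#'   \code{variance_explained} (first eigenvalue over 4).
#' @examples
#' mh <- simulate_mental_health(200, seed = 3)
#' pc <- compute_pc1(mh)
#' pc$variance_explained
#' @export
compute_pc1 <- function(records, na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  vars <- c("epds", "pss", "stai_state", "stai_trait")
  miss <- setdiff(c("subject_id", vars), names(records))
  if (length(miss))
    stop("`records` lacks column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(records[vars])
  complete <- stats::complete.cases(X)
  omitted <- character()
  if (!all(complete)) {
    ids <- as.character(records$subject_id[!complete])
    if (na_action == "error")
      stop("incomplete mental-health record(s) for subject(s): ",
           paste(ids, collapse = ", "))
    omitted <- ids
    X <- X[complete, , drop = FALSE]
    records <- records[complete, , drop = FALSE]
  }
  if (nrow(X) < 5) stop("need at least 5 complete records for PCA.")
  ranges <- mh_instruments()
  for (k in seq_along(vars)) {
    v <- X[, k]
    if (any(v < ranges$lo[k] - 1e-9 | v > ranges$hi[k] + 1e-9))
      stop(sprintf("%s values outside the instrument range [%g, %g].",
                   vars[k], ranges$lo[k], ranges$hi[k]))
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(vars[sds == 0], collapse = ", "))
  Z <- scale(X)                       # center, SD 1 with n-1 denominator
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1          # higher score = more symptoms
  scores <- drop(Z %*% v1)
  structure(list(
    scores = stats::setNames(scores, as.character(records$subject_id)),
    loadings = stats::setNames(v1, vars),
    variance_explained = ev$values[1] / length(vars)),
    class = "fcg_pc1", omitted = omitted)
}

#' @export
print.fcg_pc1 <- function(x, ...) {
  cat("Maternal mental-health composite (PC1)\n")
  cat(sprintf("  %d subjects; PC1 explains %.1f%% of total variance\n",
              length(x$scores), 100 * x$variance_explained))
  cat("  loadings: ",
      paste(sprintf("%s %.2f", names(x$loadings), x$loadings),
            collapse = ", "), "\n", sep = "")
  om <- attr(x, "omitted")
  if (length(om))
    cat("  omitted (incomplete): ", paste(om, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Covariate table from a composite result
#'
#' @param pc1 An \code{"fcg_pc1"} object.
#' @return data.frame (\code{subject_id}, \code{pc1}) suitable as the
#'   \code{covariate} argument of \code{\link{pspline_growth}}.
#' @export
pc1_covariate <- function(pc1) {
  data.frame(subject_id = names(pc1$scores), pc1 = unname(pc1$scores),
             stringsAsFactors = FALSE)
}
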