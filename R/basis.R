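#' B-spline basis specification for the growth model
#'
#' Defines the spline basis used for the population mean trajectory: a
#' B-spline with one knot at every week of postmenstrual age (PMA) from 30
#' through 44 weeks, cubic by default, with replicated boundary knots so the
#' basis spans exactly \code{[min(knots), max(knots)]}.
#'
#' With weekly knots 30..44 and cubic degree the basis has
#' \eqn{K = 13 + 3 + 1 = 17} columns (13 interior knots plus degree plus one).
#'
#' @param knots Strictly increasing knot ages in PMA weeks.
#' @param degree Polynomial degree of the spline pieces (>= 1); cubic default.
#' @return An object of class \code{"growth_basis"}.
#' @examples
#' sp <- growth_basis()
#' ncol(build_basis(c(32, 40), sp))  # 17
#' @export
growth_basis <- function(knots = 30:44, degree = 3) {
  knots <- as.numeric(knots)
  if (length(knots) < 2 || any(diff(knots) <= 0))
    stop("`knots` must be strictly increasing with at least two values.")
  if (degree < 1) stop("`degree` must be >= 1.")
  structure(list(knots = knots, degree = as.integer(degree)),
            class = "growth_basis")
}

#' Evaluate the growth-model B-spline basis at a set of ages
#'
#' Rows form a partition of unity (they sum to one) everywhere inside the
#' knot span. Ages slightly outside the span are clamped to the nearest
#' boundary knot, giving constant extrapolation; this accommodates neonatal
#' scans falling a few weeks past the last knot. Ages more than
#' \code{clamp_slack} weeks outside the span are rejected.
#'
#' @param ages Numeric vector of PMA weeks.
#' @param spec A \code{\link{growth_basis}} specification.
#' @param clamp_slack Maximum distance (weeks) beyond the knot span that is
#'   tolerated by clamping; beyond it evaluation errors.
#' @return Numeric matrix, \code{length(ages)} rows by K columns.
#' @export
build_basis <- function(ages, spec = growth_basis(), clamp_slack = 4) {
  if (!inherits(spec, "growth_basis")) stop("`spec` must be a growth_basis.")
  ages <- as.numeric(ages)
  if (any(!is.finite(ages))) stop("`ages` must be finite.")
  lo <- min(spec$knots); hi <- max(spec$knots)
  far <- ages < lo - clamp_slack | ages > hi + clamp_slack
  if (any(far))
    stop(sprintf("ages outside the supported range [%g, %g]: %s",
                 lo - clamp_slack, hi + clamp_slack,
                 paste(format(ages[far]), collapse = ", ")))
  x <- pmin(pmax(ages, lo), hi)
  ord <- spec$degree + 1L
  aknots <- c(rep(lo, ord), spec$knots[-c(1L, length(spec$knots))],
              rep(hi, ord))
  B <- splines::splineDesign(aknots, x, ord = ord, outer.ok = FALSE)
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}

#' Second-order difference matrix
#'
#' Returns the (K-2) x K matrix \code{D} with rows \code{(1, -2, 1)} so that
#' \code{D \%*\% beta} gives the second differences of a coefficient vector.
#' A Gaussian prior on these differences is the P-spline roughness penalty:
#' it shrinks the fitted curve toward piecewise linearity, with the penalty
#' standard deviation estimated from the data.
#'
#' @param K Number of spline coefficients (>= 3).
#' @return A dense (K-2) x K matrix.
#' @examples
#' second_difference_matrix(3)           # one row: 1 -2 1
#' @export
second_difference_matrix <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 3) stop("`K` must be an integer >= 3.")
  D <- matrix(0, K - 2L, K)
  for (k in seq_len(K - 2L)) D[k, k:(k + 2L)] <- c(1, -2, 1)
  D
}
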