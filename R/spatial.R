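# Anatomically informed spatial prior over per-location slopes/intercepts.

#' Spatial correlation between two visual-field locations
#'
#' Correlation kernel in Euclidean distance `d` (degrees) and nerve-fibre
#' entry-angle difference `dtheta` (degrees). Locations in different
#' hemifields are uncorrelated (the nerve-fibre anatomy does not cross the
#' horizontal midline); this is handled by [buildSpatialPrior()], which
#' zeroes cross-hemifield entries.
#'
#' @param d Euclidean distance(s) in degrees (>= 0).
#' @param dtheta absolute fibre-angle difference(s) in degrees (>= 0).
#' @param sigmaD distance scale (degrees), default 6 (neighbour spacing).
#' @param sigmaTheta angle scale (degrees), default 15.
#' @param kernel "squared_exponential" (default) or "exponential".
#' @return correlation value(s) in [0, 1].
#' @examples
#' spatialCorrelation(6, 0)           # exp(-1/2)
#' spatialCorrelation(0, 0)           # 1
#' @export
spatialCorrelation <- function(d, dtheta, sigmaD = 6, sigmaTheta = 15,
                               kernel = c("squared_exponential",
                                          "exponential")) {
  kernel <- match.arg(kernel)
  stopifnot(sigmaD > 0, sigmaTheta > 0)
  if (kernel == "squared_exponential")
    exp(-d^2 / (2 * sigmaD^2) - dtheta^2 / (2 * sigmaTheta^2))
  else
    exp(-d / sigmaD - dtheta / sigmaTheta)
}

#' Build the spatial prior over slopes and intercepts
#'
#' Assembles the unscaled correlation matrix Psi from
#' [spatialCorrelation()], zeroing all cross-hemifield entries, and attaches
#' the covariance scales: the slope prior is MVN(slopeMean, a * Psi) with
#' `a = slopeSD^2`, the intercept prior MVN(interceptMean, b * Psi) with
#' `b = interceptSD^2`. Defaults give weakly informative priors: a 10
#' dB/year slope SD, a 10 dB intercept SD, and an intercept mean at the
#' middle of the 0-35 dB measurement range.
#'
#' @param grid a \linkS4class{VisualFieldGrid}.
#' @param sigmaD,sigmaTheta kernel scales in degrees.
#' @param slopeSD,interceptSD prior marginal standard deviations.
#' @param slopeMean,interceptMean prior means (dB/year, dB).
#' @param kernel kernel form, see [spatialCorrelation()].
#' @param spatial if FALSE, Psi is the identity (the no-spatial "ANSWER"
#'   variant of the prior).
#' @param jitter ridge added to Psi to guarantee positive definiteness.
#' @return a \linkS4class{SpatialPrior}. Note the jitter is NOT folded into
#'   `psi` (which keeps a unit diagonal); it is applied when the prior is
#'   inverted.
#' @export
buildSpatialPrior <- function(grid, sigmaD = 6, sigmaTheta = 15,
                              slopeSD = 10, interceptSD = 10,
                              slopeMean = 0, interceptMean = 17.5,
                              kernel = c("squared_exponential",
                                         "exponential"),
                              spatial = TRUE, jitter = 1e-8) {
  kernel <- match.arg(kernel)
  loc <- locations(grid)
  m <- nrow(loc)
  if (spatial) {
    d <- locationDistances(grid)
    dth <- abs(outer(loc$fibre_angle_deg, loc$fibre_angle_deg, "-"))
    same <- outer(loc$hemifield, loc$hemifield, "==")
    p <- spatialCorrelation(d, dth, sigmaD, sigmaTheta, kernel) * same
    diag(p) <- 1
    ev <- eigen(p, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf(
        "spatial correlation matrix is not positive semi-definite beyond the jitter policy (min eigenvalue %.3e, condition %.3e)",
        min(ev), max(ev) / max(min(ev), .Machine$double.eps)))
  } else {
    p <- diag(m)
  }
  dimnames(p) <- NULL
  new("SpatialPrior", psi = p, a = slopeSD^2, b = interceptSD^2,
      muSlope = slopeMean, muIntercept = interceptMean,
      sigmaD = sigmaD, sigmaTheta = sigmaTheta,
      kernel = if (spatial) kernel else "identity")
}

#' Drop the spatial coupling from a prior (ANSWER variant)
#'
#' Returns the prior with all off-diagonal entries of Psi set to zero, so
#' the posterior factorises across locations.
#'
#' @param prior a \linkS4class{SpatialPrior}.
#' @return a \linkS4class{SpatialPrior} with diagonal Psi.
#' @export
dropSpatial <- function(prior) {
  p <- diag(nrow(psi(prior)))
  new("SpatialPrior", psi = p, a = prior@a, b = prior@b,
      muSlope = prior@muSlope, muIntercept = prior@muIntercept,
      sigmaD = prior@sigmaD, sigmaTheta = prior@sigmaTheta,
      kernel = "identity")
}

# Inverse of (psi + jitter I); errors with a condition report if singular.
.psiInverse <- function(prior, jitter = 1e-8) {
  p <- psi(prior) + jitter * diag(nrow(psi(prior)))
  ch <- tryCatch(chol(p), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(p, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(
      "prior covariance is singular after jitter (eigenvalue range [%.3e, %.3e])",
      min(ev), max(ev)))
  }
  chol2inv(ch)
}
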