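# The inferential engine: series likelihood under the retest model,
# spatially coupled MAP regression, Laplace covariance, Pnd and the global
# deterioration / improvement indices.

# Build the fast posterior objective for one series: per-observation splines
# of log p(y | mu) over a shared predicted-level grid, plus the Gaussian
# prior terms. Returns fn/gr closures over par = c(slopes, intercepts).
.posteriorObjective <- function(series, retest, prior, gridBy = 0.25,
                                sharpness = 10, jitter = 1e-8) {
  m <- nLocations(series)
  q <- length(series@times)
  lo <- min(retest@levels); hi <- max(retest@levels)
  psiInv <- .psiInverse(prior, jitter)
  Qs <- psiInv / prior@a
  Qi <- psiInv / prior@b
  muS <- rep(prior@muSlope, m)
  muI <- rep(prior@muIntercept, m)

  if (q > 0) {
    yt <- transformDls(as.vector(series@values), retest@transformKnot)
    tObs <- rep(series@times, times = m)
    locIdx <- rep(seq_len(m), each = q)
    muGrid <- seq(lo, hi, by = gridBy)
    par <- .parameterInterpolator(retest)(muGrid)
    nG <- length(muGrid); nO <- length(yt)
    gIdx <- rep(seq_len(nG), each = nO)
    lds <- lapply(seq_len(retest@K), function(k) {
      matrix(log(par$weights[, k])[gIdx] +
               .ldweibull(rep(yt, nG), par$alphas[, k][gIdx],
                          par$betas[, k][gIdx]),
             nO, nG)
    })
    mx <- pmax(Reduce(pmax, lds), -745)
    G <- mx + log(Reduce(`+`, lapply(lds, function(x) exp(x - mx))))
    G <- pmax(G, -700)
    sp <- .rowSplineCoefs(muGrid, G)
  }

  evalBoth <- function(p) {
    s <- p[seq_len(m)]
    c0 <- p[m + seq_len(m)]
    ds <- s - muS; di <- c0 - muI
    gs <- -as.vector(Qs %*% ds)
    gi <- -as.vector(Qi %*% di)
    val <- -0.5 * sum(ds * -gs) - 0.5 * sum(di * -gi)
    if (q > 0) {
      mu <- c0[locIdx] + s[locIdx] * tObs
      if (any(!is.finite(mu))) stop("non-finite predicted level")
      cl <- smoothClamp(mu, lo, hi, sharpness)
      ev <- .rowSplineEval(sp, cl$value)
      val <- val + sum(ev$value)
      gmu <- ev$deriv * cl$deriv
      gs <- gs + as.vector(rowsum(gmu * tObs, locIdx, reorder = TRUE))
      gi <- gi + as.vector(rowsum(gmu, locIdx, reorder = TRUE))
    }
    list(value = val, gradient = c(gs, gi))
  }
  list(fn = function(p) evalBoth(p)$value,
       gr = function(p) evalBoth(p)$gradient,
       m = m)
}

#' Posterior objective for a series (value and gradient closures)
#'
#' Exposes the log-posterior objective (up to an additive constant) that
#' [mapEstimate()] maximises, as value and gradient functions over the
#' parameter vector `c(slopes, intercepts)`. Mainly useful for numerical
#' checks.
#'
#' @param series a \linkS4class{VFSeries} (Q = 0 gives the prior alone).
#' @param retest a \linkS4class{RetestModel}.
#' @param prior a \linkS4class{SpatialPrior}.
#' @return list with functions `fn(par)` and `gr(par)`.
#' @export
posteriorObjective <- function(series, retest, prior)
  .posteriorObjective(series, retest, prior)[c("fn", "gr")]

#' Series log-likelihood under the retest model
#'
#' Sum over tests and locations of `log p(y_ij | mu_ij)` with
#' `mu_ij = intercept_j + slope_j * t_i`, the predicted level smoothly
#' clamped into the modelled range for the density lookup. Direct
#' evaluation through the interpolated mixture (no grid splines).
#'
#' @param series a \linkS4class{VFSeries}.
#' @param slopes,intercepts per-location regression weights.
#' @param retest a \linkS4class{RetestModel}.
#' @return the log-likelihood.
#' @export
seriesLogLikelihood <- function(series, slopes, intercepts, retest) {
  q <- length(series@times)
  if (q == 0) return(0)
  m <- nLocations(series)
  mu <- rep(intercepts, each = q) + rep(slopes, each = q) * rep(series@times, m)
  if (any(!is.finite(mu))) stop("non-finite predicted level")
  sum(retestLogDensity(retest, as.vector(series@values), mu))
}

#' Series log-posterior (up to a constant)
#'
#' [seriesLogLikelihood()] plus the log multivariate-normal prior densities
#' of the slope and intercept vectors (MVN(muSlope, a Psi) and
#' MVN(muIntercept, b Psi)), additive constants dropped.
#'
#' @inheritParams seriesLogLikelihood
#' @param prior a \linkS4class{SpatialPrior}.
#' @return the log posterior up to an additive constant.
#' @export
seriesLogPosterior <- function(series, slopes, intercepts, retest, prior) {
  psiInv <- .psiInverse(prior)
  ds <- slopes - prior@muSlope
  di <- intercepts - prior@muIntercept
  seriesLogLikelihood(series, slopes, intercepts, retest) -
    0.5 * sum(ds * (psiInv %*% ds)) / prior@a -
    0.5 * sum(di * (psiInv %*% di)) / prior@b
}

#' Maximum a posteriori estimate of per-location trends
#'
#' Quasi-Newton (BFGS) maximisation of the log posterior over the 2M
#' parameters (slopes, intercepts). Initialised at per-location ordinary
#' least squares on transformed sensitivities, shrunk half-way toward the
#' prior means.
#'
#' @param series a \linkS4class{VFSeries} with at least 3 tests.
#' @param retest a \linkS4class{RetestModel}.
#' @param prior a \linkS4class{SpatialPrior}.
#' @param init optional starting vector `c(slopes, intercepts)`.
#' @param maxIter iteration cap per BFGS round.
#' @param gtol gradient max-norm declaring convergence.
#' @param maxRounds BFGS polish rounds.
#' @return list with `slopes`, `intercepts`, `logPosterior`, `converged`
#'   and `gradNorm`.
#' @export
mapEstimate <- function(series, retest, prior, init = NULL,
                        maxIter = 1000, gtol = 1e-6, maxRounds = 4) {
  q <- length(series@times)
  if (q < 3) stop("at least 3 tests are required for analysis")
  m <- nLocations(series)
  obj <- .posteriorObjective(series, retest, prior)
  if (is.null(init)) {
    # slopes shrunk half-way to the prior mean; intercepts kept at their OLS
    # values (shrinking them toward mid-range strands healthy locations in a
    # low-likelihood region between the healthy and damaged density modes)
    yt <- matrix(transformDls(as.vector(series@values),
                              retest@transformKnot), nrow = q)
    co <- matrix(stats::coef(stats::lm(yt ~ series@times)), nrow = 2)
    init <- c(0.5 * co[2, ] + 0.5 * rep(prior@muSlope, m),
              pmin(pmax(co[1, ], 0), 35))
  }
  negfn <- function(p) -obj$fn(p)
  neggr <- function(p) -obj$gr(p)
  par <- init
  converged <- FALSE
  for (round in seq_len(maxRounds)) {
    res <- tryCatch(
      stats::optim(par, negfn, neggr, method = "BFGS",
                   control = list(maxit = maxIter, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) {             # line-search failure: restart from prior
      par <- c(rep(prior@muSlope, m), rep(prior@muIntercept, m))
      res <- stats::optim(par, negfn, neggr, method = "BFGS",
                          control = list(maxit = maxIter, reltol = 1e-14))
    }
    newPar <- res$par
    gn <- max(abs(obj$gr(newPar)))
    improved <- max(abs(newPar - par)) > 0
    par <- newPar
    if (gn < gtol) { converged <- TRUE; break }
    if (!improved) break
  }
  if (!converged && gn > 1e-3)
    warning(sprintf("MAP optimisation did not converge (gradient max-norm %.2e)", gn))
  list(slopes = par[seq_len(m)], intercepts = par[m + seq_len(m)],
       logPosterior = obj$fn(par), converged = converged || gn < 1e-3,
       gradNorm = gn)
}

#' Laplace covariance of the trend parameters
#'
#' Inverse of the negative Hessian of the log posterior at the mode, the
#' Hessian obtained by central finite differences of the analytic gradient
#' (step 1e-4) and symmetrised. Positive semi-definiteness is enforced by
#' clipping eigenvalues of the negative Hessian at 1e-10 (with a warning);
#' clearly indefinite Hessians raise an error reporting the offending
#' eigenvalues.
#'
#' @inheritParams mapEstimate
#' @param slopes,intercepts the MAP mode.
#' @param step finite-difference step.
#' @return 2M x 2M covariance matrix (slopes first).
#' @export
laplaceCovariance <- function(series, slopes, intercepts, retest, prior,
                              step = 1e-4) {
  obj <- .posteriorObjective(series, retest, prior)
  p0 <- c(slopes, intercepts)
  n <- length(p0)
  H <- matrix(0, n, n)
  for (k in seq_len(n)) {
    e <- rep(0, n); e[k] <- step
    H[, k] <- (obj$gr(p0 + e) - obj$gr(p0 - e)) / (2 * step)
  }
  H <- (H + t(H)) / 2
  negH <- -H
  ed <- eigen(negH, symmetric = TRUE)
  # small negative eigenvalues arise at near-flat (clamp-saturated)
  # directions of imperfectly converged modes; clipping them to the floor
  # yields a huge, i.e. conservative, variance along those directions
  tolBig <- 1e-4 * max(abs(ed$values))
  if (any(ed$values < -tolBig))
    stop("indefinite Hessian at the supplied mode; offending eigenvalues: ",
         paste(signif(ed$values[ed$values < -tolBig], 4), collapse = ", "))
  if (any(ed$values < 1e-10)) {
    warning("clipping near-zero Hessian eigenvalues for the Laplace covariance")
    ed$values <- pmax(ed$values, 1e-10)
  }
  cov <- ed$vectors %*% (t(ed$vectors) / ed$values)
  (cov + t(cov)) / 2
}

#' Probability of no deterioration
#'
#' Under the Laplace normal approximation of the slope marginal,
#' `P(slope >= 0) = pnorm(slopeMean / slopeSD)`, clamped away from 0 so its
#' logarithm stays finite.
#'
#' @param slopeMean posterior mean slope(s), dB/year.
#' @param slopeSD posterior slope standard deviation(s), > 0.
#' @return probabilities in [1e-300, 1].
#' @export
pndFromSlope <- function(slopeMean, slopeSD) {
  stopifnot(all(slopeSD > 0))
  pmin(pmax(stats::pnorm(slopeMean / slopeSD), 1e-300), 1)
}

#' Global deterioration index from per-location Pnd values
#'
#' The negative logarithm of the product of the Pnd values: non-negative,
#' additive over locations, larger when deterioration is more certain.
#'
#' @param pndValues probabilities in (0, 1].
#' @return the index (>= 0).
#' @export
sIndex <- function(pndValues) {
  stopifnot(all(pndValues >= 0), all(pndValues <= 1))
  if (any(pndValues == 0)) {
    warning("Pnd of exactly 0 clamped to the floor (1e-300)")
    pndValues <- pmax(pndValues, 1e-300)
  }
  -sum(log(pndValues))
}

#' Analyse a visual-field series for deterioration
#'
#' Full pipeline: MAP trend estimation, Laplace covariance, per-location
#' probability of no deterioration from the marginal slope distribution,
#' and the global deterioration (`S_d`) and improvement (`S_i`) indices.
#' `mode = "ANSWER"` zeroes the off-diagonal spatial coupling of the prior.
#'
#' @inheritParams mapEstimate
#' @param mode "ANSWERS" (spatial prior) or "ANSWER" (diagonal prior).
#' @return a \linkS4class{PosteriorEstimate}.
#' @examples
#' \donttest{
#' grid <- buildGrid()
#' retest <- readRetestModel(system.file("extdata",
#'   "retest_model_synthetic.json", package = "answers"))
#' prior <- buildSpatialPrior(grid)
#' cohort <- genCohort(generatorConfig(nEyes = 1, propProgressing = 1,
#'                                     seed = 7), grid)
#' est <- analyzeSeries(cohort$series[[1]], retest, prior)
#' deteriorationIndex(est)
#' }
#' @export
analyzeSeries <- function(series, retest, prior,
                          mode = c("ANSWERS", "ANSWER"), init = NULL,
                          gtol = 1e-6) {
  mode <- match.arg(mode)
  if (mode == "ANSWER") prior <- dropSpatial(prior)
  fit <- mapEstimate(series, retest, prior, init = init, gtol = gtol)
  cov <- tryCatch(
    laplaceCovariance(series, fit$slopes, fit$intercepts, retest, prior),
    error = function(e) {
      # re-polish the mode once from a jittered start, then retry
      fit2 <- mapEstimate(series, retest, prior,
                          init = c(fit$slopes, fit$intercepts) +
                            1e-3 * sin(seq_along(c(fit$slopes, fit$intercepts))),
                          gtol = gtol, maxRounds = 8)
      if (fit2$logPosterior >= fit$logPosterior) fit <<- fit2
      laplaceCovariance(series, fit$slopes, fit$intercepts, retest, prior)
    })
  m <- length(fit$slopes)
  sds <- sqrt(pmax(diag(cov)[seq_len(m)], 1e-300))
  p <- pndFromSlope(fit$slopes, sds)
  new("PosteriorEstimate",
      slopes = fit$slopes, intercepts = fit$intercepts, covariance = cov,
      pnd = p, sD = sIndex(p), sI = sIndex(pmax(1 - p, 1e-300)),
      logPosterior = fit$logPosterior, converged = fit$converged,
      mode = mode, eyeId = series@eyeId)
}
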