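# Weibull mixture fitting by expectation-maximisation, and the low-end
# sensitivity transform that keeps log-Weibull densities defined at 0 dB.

#' Low-end sensitivity transform
#'
#' Maps measured sensitivity (dB) onto the strictly positive support of the
#' Weibull mixtures: the identity at and above the knot (1 dB by default),
#' and `knot * exp((y - knot)/knot)` below it. The map is continuous with a
#' continuous first derivative at the knot and is strictly positive, so a
#' floor measurement of 0 dB keeps a finite log density.
#'
#' @param y sensitivities in dB (>= 0).
#' @param knot transition point in dB.
#' @return transformed values (> 0).
#' @examples
#' transformDls(c(0, 1, 20))  # exp(-1), 1, 20
#' @export
transformDls <- function(y, knot = 1) {
  if (any(y < 0)) stop("sensitivities must be non-negative")
  ifelse(y >= knot, y, knot * exp((y - knot) / knot))
}

#' Construct a Weibull mixture
#'
#' @param weights mixing proportions (non-negative, sum to 1).
#' @param alphas shape parameters (> 0).
#' @param betas scale parameters (> 0, dB).
#' @return a list of class `WeibullMixture`.
#' @export
weibullMixture <- function(weights, alphas, betas) {
  stopifnot(length(weights) == length(alphas),
            length(alphas) == length(betas),
            all(weights >= 0), abs(sum(weights) - 1) < 1e-8,
            all(alphas > 0), all(betas > 0))
  structure(list(weights = as.numeric(weights), alphas = as.numeric(alphas),
                 betas = as.numeric(betas)), class = "WeibullMixture")
}

#' Weibull mixture density
#'
#' Density of a K-component Weibull mixture (shape/scale parameterisation,
#' so the K = 1, shape 1 case is the exponential distribution).
#'
#' @param y evaluation points (>= 0).
#' @param mixture a [weibullMixture()].
#' @param log return the log density.
#' @return density values.
#' @export
dweibullMixture <- function(y, mixture, log = FALSE) {
  if (any(y < 0)) stop("density is defined for non-negative values only")
  ld <- vapply(seq_along(mixture$weights), function(k) {
    log(mixture$weights[k]) +
      .ldweibull(y, mixture$alphas[k], mixture$betas[k])
  }, numeric(length(y)))
  ld <- matrix(ld, nrow = length(y))
  out <- .logSumExpRows(ld)
  out[is.nan(out)] <- -Inf
  if (log) out else exp(out)
}

#' Log-likelihood of data under a Weibull mixture
#' @param y positive data values.
#' @param mixture a [weibullMixture()].
#' @return total log-likelihood.
#' @export
weibullMixtureLogLik <- function(y, mixture)
  sum(dweibullMixture(y, mixture, log = TRUE))

# Log Weibull density computed analytically: unlike dweibull(log = TRUE),
# never NaN when (x/scale)^shape overflows (returns -Inf instead).
.ldweibull <- function(x, shape, scale) {
  n <- max(length(x), length(shape), length(scale))
  x <- rep_len(x, n); shape <- rep_len(shape, n); scale <- rep_len(scale, n)
  lr <- log(x) - log(scale)
  out <- log(shape) - log(scale) + (shape - 1) * lr - exp(shape * lr)
  z <- x == 0                      # limit at the origin depends on the shape
  if (any(z)) out[z] <- ifelse(shape[z] > 1, -Inf,
                               ifelse(shape[z] == 1, -log(scale[z]), Inf))
  out
}

# Weighted Weibull maximum likelihood (shape by 1-D root-find on the profile
# likelihood equation, scale in closed form given the shape).
.weibullMLE <- function(y, w = rep(1, length(y))) {
  keep <- w > 0
  y <- y[keep]; w <- w[keep]
  if (length(y) < 2 || stats::sd(y) == 0)
    return(list(alpha = 100, beta = max(mean(y), .Machine$double.eps)))
  ly <- log(y)
  lmax <- max(ly)
  lz <- ly - lmax                       # log(y/ymax), <= 0: no overflow
  sw <- sum(w)
  mlw <- sum(w * ly) / sw
  g <- function(a) {
    za <- exp(a * lz)
    sum(w * za * ly) / sum(w * za) - 1 / a - mlw
  }
  lo <- 0.05; hi <- 2
  while (g(hi) < 0 && hi < 500) hi <- hi * 2
  hi <- min(hi, 500)
  a <- if (g(lo) > 0) lo
       else if (g(hi) < 0) hi
       else stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  b <- exp(lmax) * (sum(w * exp(a * lz)) / sw)^(1 / a)
  list(alpha = a, beta = b)
}

.mstep <- function(y, resp) {
  K <- ncol(resp)
  w <- colMeans(resp)
  al <- be <- numeric(K)
  for (k in seq_len(K)) {
    fit <- .weibullMLE(y, resp[, k])
    al[k] <- fit$alpha; be[k] <- fit$beta
  }
  list(weights = w, alphas = al, betas = be)
}

.estepLogLik <- function(y, par) {
  ld <- vapply(seq_along(par$weights), function(k) {
    log(par$weights[k]) + .ldweibull(y, par$alphas[k], par$betas[k])
  }, numeric(length(y)))
  ld <- matrix(ld, nrow = length(y))
  rowll <- .logSumExpRows(ld)
  list(resp = exp(ld - rowll), logLik = sum(rowll))
}

.emOnce <- function(y, init, maxIter, tol) {
  par <- init
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    e <- .estepLogLik(y, par)
    if (!is.finite(e$logLik)) stop("non-finite likelihood in EM")
    trace <- c(trace, e$logLik)
    if (it > 1 && (e$logLik - trace[it - 1]) < tol) break
    par <- .mstep(y, e$resp)
    # prune degenerate components
    if (any(par$weights < 1e-6) && length(par$weights) > 1) {
      warning("pruning degenerate mixture component (weight < 1e-6)")
      keep <- par$weights >= 1e-6
      par <- list(weights = par$weights[keep] / sum(par$weights[keep]),
                  alphas = par$alphas[keep], betas = par$betas[keep])
    }
  }
  list(par = par, logLik = trace[length(trace)], trace = trace,
       iterations = length(trace))
}

.quantileInit <- function(y, K) {
  if (K == 1) {
    fit <- .weibullMLE(y)
    return(list(weights = 1, alphas = fit$alpha, betas = fit$beta))
  }
  o <- order(y)
  blocks <- split(y[o], cut(seq_along(o), K, labels = FALSE))
  al <- be <- numeric(K)
  for (k in seq_len(K)) {
    fit <- .weibullMLE(blocks[[k]])
    al[k] <- fit$alpha; be[k] <- fit$beta
  }
  list(weights = rep(1 / K, K), alphas = al, betas = be)
}

#' Fit a Weibull mixture by expectation-maximisation
#'
#' Iterates E (responsibilities) and M (closed-form mixing proportions,
#' weighted Weibull maximum likelihood for each component) steps until the
#' log-likelihood gain falls below `tol`. The first start splits the data
#' into K quantile blocks; the remaining restarts use random
#' responsibilities; the best final likelihood is kept. Input values must be
#' positive, i.e. already passed through [transformDls()].
#'
#' @param y positive data values (transformed sensitivities).
#' @param K number of mixture components.
#' @param maxIter,tol EM stopping rule (log-likelihood gain).
#' @param nRestarts number of EM starts.
#' @param seed RNG seed for the random restarts.
#' @param init optional warm start (list with weights/alphas/betas of
#'   length K), used as the first start.
#' @return list with `mixture` (a [weibullMixture()], components ordered by
#'   ascending scale), `logLik`, `trace` (per-iteration log-likelihood of
#'   the best start) and `iterations`.
#' @export
emFitWeibullMixture <- function(y, K, maxIter = 500, tol = 1e-8,
                                nRestarts = 5, seed = 1, init = NULL) {
  stopifnot(all(y > 0), K >= 1)
  if (length(y) < 10 * K)
    stop(sprintf("need at least %d observations to fit %d components",
                 10 * K, K))
  if (K == 1) nRestarts <- 1
  starts <- c(if (!is.null(init)) list(init), list(NULL))
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(max(nRestarts, length(starts)))) {
      init <- if (r <= length(starts) && !is.null(starts[[r]])) starts[[r]]
      else if (r == length(starts)) .quantileInit(y, K)
      else {
        resp <- matrix(stats::rexp(length(y) * K), ncol = K)
        resp <- resp / rowSums(resp)
        .mstep(y, resp)
      }
      fit <- tryCatch(.emOnce(y, init, maxIter, tol),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik))
        best <- fit
    }
  })
  if (is.null(best)) stop("EM failed for every start")
  o <- order(best$par$betas)
  list(mixture = weibullMixture(best$par$weights[o], best$par$alphas[o],
                                best$par$betas[o]),
       logLik = best$logLik, trace = best$trace,
       iterations = best$iterations)
}

#' Select the Weibull mixture component count by cross-validation
#'
#' Starting from K = 1, the component count is increased while the held-out
#' log-likelihood of the (K+1)-component mixture exceeds that of the
#' K-component mixture with statistical significance (one-sided paired
#' t-test over folds, p < `alpha`).
#'
#' @param y positive data values (transformed sensitivities).
#' @param kMax largest component count considered.
#' @param nFolds cross-validation folds.
#' @param alpha significance level of the improvement test (default 1%).
#' @param seed RNG seed (fold assignment and EM restarts).
#' @param nRestarts EM restarts per fold fit.
#' @return the selected component count.
#' @export
selectComponentCount <- function(y, kMax = 4, nFolds = 5, alpha = 0.01,
                                 seed = 1, nRestarts = 3) {
  stopifnot(length(y) >= 50, kMax >= 1)
  if (kMax == 1) return(1L)
  folds <- .withSeed(seed, sample(rep_len(seq_len(nFolds), length(y))))
  heldOut <- function(K) {
    vapply(seq_len(nFolds), function(f) {
      tr <- y[folds != f]; te <- y[folds == f]
      fit <- tryCatch(
        emFitWeibullMixture(tr, K, maxIter = 200, tol = 1e-6,
                            nRestarts = nRestarts, seed = seed + f),
        error = function(e) {
          warning(sprintf("EM failed in fold %d for K = %d: %s",
                          f, K, conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) NA_real_
      else weibullMixtureLogLik(te, fit$mixture) / length(te)
    }, numeric(1))
  }
  cur <- heldOut(1)
  if (all(is.na(cur))) stop("EM failed in every cross-validation fold")
  K <- 1L
  while (K < kMax) {
    nxt <- heldOut(K + 1L)
    ok <- is.finite(cur) & is.finite(nxt)
    if (sum(ok) < 2) break
    d <- nxt[ok] - cur[ok]
    p <- if (stats::sd(d) == 0) {
      if (mean(d) > 0) 0 else 1
    } else {
      stats::t.test(d, alternative = "greater")$p.value
    }
    if (p >= alpha) break
    K <- K + 1L
    cur <- nxt
  }
  K
}
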