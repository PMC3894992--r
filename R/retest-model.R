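# Per-level retest distributions: fitting, interpolation across levels,
# and (de)serialisation.

#' Construct a RetestModel from per-level mixture parameters
#'
#' @param weights,alphas,betas L x K matrices of mixture parameters, one row
#'   per integer level in `levels`.
#' @param levels integer sensitivity levels covered (default 0:35 dB).
#' @param selectedK component count chosen by cross-validation, if any.
#' @param transformKnot knot of [transformDls()] used when fitting.
#' @return a \linkS4class{RetestModel}.
#' @export
retestModel <- function(weights, alphas, betas, levels = 0:35,
                        selectedK = NA_integer_, transformKnot = 1) {
  weights <- as.matrix(weights); alphas <- as.matrix(alphas)
  betas <- as.matrix(betas)
  new("RetestModel", levels = as.integer(levels), weights = weights,
      alphas = alphas, betas = betas, K = ncol(weights),
      selectedK = as.integer(selectedK), transformKnot = transformKnot)
}

# Natural cubic interpolators of the mixture parameters across levels:
# weights through additive log-ratio space, shapes and scales in log space.
# Returns a function(mu) -> list(weights, alphas, betas), each |mu| x K.
.parameterInterpolator <- function(model) {
  lv <- model@levels
  K <- model@K
  w <- pmax(model@weights, 1e-12)
  lw <- log(w) - log(w[, K])            # alr coordinates, last = 0
  fw <- lapply(seq_len(K - 1), function(k)
    stats::splinefun(lv, lw[, k], method = "natural"))
  fa <- lapply(seq_len(K), function(k)
    stats::splinefun(lv, log(model@alphas[, k]), method = "natural"))
  fb <- lapply(seq_len(K), function(k)
    stats::splinefun(lv, log(model@betas[, k]), method = "natural"))
  function(mu) {
    n <- length(mu)
    lwm <- matrix(0, n, K)
    if (K > 1)
      for (k in seq_len(K - 1)) lwm[, k] <- fw[[k]](mu)
    wm <- exp(lwm - .logSumExpRows(lwm))
    # clamp against spline overshoot so densities stay well defined
    am <- vapply(fa, function(f) pmin(pmax(exp(f(mu)), 0.05), 500),
                 numeric(n))
    bm <- vapply(fb, function(f) pmin(pmax(exp(f(mu)), 0.01), 500),
                 numeric(n))
    list(weights = matrix(wm, n, K), alphas = matrix(am, n, K),
         betas = matrix(bm, n, K))
  }
}

# Log mixture density of transformed observations `yt` (vector, recycled
# against mu) at interpolated parameters for predicted levels `mu` (already
# clamped into the modelled range).
.logDensityAt <- function(model, yt, mu, interp = NULL) {
  if (is.null(interp)) interp <- .parameterInterpolator(model)
  par <- interp(mu)
  n <- max(length(yt), length(mu))
  yt <- rep_len(yt, n)
  ld <- vapply(seq_len(model@K), function(k) {
    log(par$weights[, k]) + .ldweibull(yt, par$alphas[, k], par$betas[, k])
  }, numeric(n))
  out <- .logSumExpRows(matrix(ld, nrow = n))
  pmax(out, -700)                        # guard against -Inf underflow
}

#' Retest log density of an observation given a predicted level
#'
#' Evaluates `log p(y | mu)`: the log density of the observed sensitivity
#' `y` under the Weibull mixture interpolated at the (continuous) predicted
#' true level `mu`. `mu` is smoothly clamped into the modelled range.
#'
#' @param model a \linkS4class{RetestModel}.
#' @param y observed sensitivities in dB (recycled against `mu`).
#' @param mu predicted levels in dB.
#' @return log densities.
#' @export
retestLogDensity <- function(model, y, mu) {
  yt <- transformDls(y, model@transformKnot)
  muc <- smoothClamp(mu, min(model@levels), max(model@levels))$value
  .logDensityAt(model, yt, muc)
}

#' Quantiles of the fitted retest distribution at a level
#'
#' @param model a \linkS4class{RetestModel}.
#' @param level integer sensitivity level.
#' @param probs quantile probabilities.
#' @return quantiles on the transformed (positive) scale.
#' @export
retestQuantiles <- function(model, level, probs = c(0.05, 0.95)) {
  i <- match(level, model@levels)
  if (is.na(i)) stop("level not covered by the model")
  mix <- weibullMixture(model@weights[i, ], model@alphas[i, ],
                        model@betas[i, ])
  cdf <- function(q) sum(mix$weights *
                           stats::pweibull(q, mix$alphas, mix$betas))
  vapply(probs, function(p)
    stats::uniroot(function(q) cdf(q) - p, c(1e-9, 200), tol = 1e-8)$root,
    numeric(1))
}

#' Fit the retest model from test-retest pairs
#'
#' For each integer sensitivity level the retest values whose baseline
#' rounds to that level are collected (pooling +-1 neighbouring levels, then
#' widening, when fewer than `minPerLevel` values are available), passed
#' through [transformDls()], and fitted with a common K-component Weibull
#' mixture by [emFitWeibullMixture()]. The common K is selected once by
#' [selectComponentCount()] on pooled samples from representative levels
#' (cross-validated improvement at the 1% significance level), unless `K`
#' is given.
#'
#' @param pairs data.frame with columns `baseline_dls` and `retest_dls`
#'   (e.g. from [genRetestPairs()] or [retestPairsFromRepeats()]).
#' @param K integer to fix the component count, or "auto".
#' @param levels integer levels to fit (default 0:35).
#' @param minPerLevel minimum values per level before pooling widens.
#' @param symmetric use each unordered pair in both directions.
#' @param maxPerLevel cap on per-level sample size (seeded subsample).
#' @param selectLevels levels used for component-count selection.
#' @param kMax,nFolds passed to [selectComponentCount()].
#' @param seed RNG seed.
#' @return a \linkS4class{RetestModel}.
#' @export
fitRetestModel <- function(pairs, K = "auto", levels = 0:35,
                           minPerLevel = 50, symmetric = TRUE,
                           maxPerLevel = 1500,
                           selectLevels = c(5, 15, 25), kMax = 4,
                           nFolds = 5, seed = 1) {
  stopifnot(all(c("baseline_dls", "retest_dls") %in% names(pairs)),
            nrow(pairs) > 0)
  b <- pairs$baseline_dls; r <- pairs$retest_dls
  if (symmetric) {
    b2 <- c(b, r); r <- c(r, b); b <- b2
  }
  lev <- pmin(pmax(round(b), min(levels)), max(levels))

  gather <- function(v) {
    width <- 0
    repeat {
      vals <- r[abs(lev - v) <= width]
      if (length(vals) >= minPerLevel || width > diff(range(levels))) break
      width <- width + 1
    }
    if (length(vals) == 0)
      stop(sprintf("no retest data available for level %d dB", v))
    vals
  }
  perLevel <- lapply(levels, gather)

  selectedK <- NA_integer_
  if (identical(K, "auto")) {
    sel <- integer(0)
    for (v in selectLevels) {
      vals <- perLevel[[match(v, levels)]]
      vals <- transformDls(vals)
      if (length(vals) > 2000)
        vals <- .withSeed(seed + v, sample(vals, 2000))
      sel <- c(sel, selectComponentCount(vals, kMax = kMax, nFolds = nFolds,
                                         seed = seed + v))
    }
    selectedK <- max(sel)
    K <- selectedK
  }
  K <- as.integer(K)

  L <- length(levels)
  W <- A <- B <- matrix(NA_real_, L, K)
  warm <- NULL
  for (i in seq_len(L)) {
    vals <- transformDls(perLevel[[i]])
    if (length(vals) > maxPerLevel)
      vals <- .withSeed(seed + 100 + i, sample(vals, maxPerLevel))
    fit <- emFitWeibullMixture(vals, K, nRestarts = 2,
                               seed = seed + 200 + i, init = warm)
    mix <- fit$mixture
    if (length(mix$weights) == K) warm <- mix
    k <- length(mix$weights)
    if (k < K) {            # a pruned component: pad without changing density
      pad <- K - k
      mix$weights <- c(rep(mix$weights[1] / (pad + 1), pad + 1),
                       mix$weights[-1])
      mix$alphas <- c(rep(mix$alphas[1], pad + 1), mix$alphas[-1])
      mix$betas <- c(rep(mix$betas[1], pad + 1), mix$betas[-1])
    }
    o <- order(mix$betas)
    W[i, ] <- mix$weights[o]; A[i, ] <- mix$alphas[o]; B[i, ] <- mix$betas[o]
  }
  retestModel(W, A, B, levels = levels, selectedK = selectedK)
}

#' Serialise / read a fitted retest model (JSON)
#'
#' @param model a \linkS4class{RetestModel}.
#' @param path file path.
#' @return `readRetestModel` returns a \linkS4class{RetestModel}.
#' @export
writeRetestModel <- function(model, path) {
  obj <- list(levels = model@levels, K = model@K,
              selectedK = if (is.na(model@selectedK)) NULL
                          else model@selectedK,
              transformKnot = model@transformKnot,
              weights = model@weights, alphas = model@alphas,
              betas = model@betas)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeRetestModel
#' @export
readRetestModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sk <- obj$selectedK
  if (length(sk) != 1 || identical(sk, "NA")) sk <- NA_integer_
  retestModel(obj$weights, obj$alphas, obj$betas, levels = obj$levels,
              selectedK = sk, transformKnot = obj$transformKnot)
}
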