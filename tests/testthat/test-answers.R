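test_that("the series likelihood factorises over tests and matches a one-term case", {
  rm <- toyRetestModel()
  g1 <- toyGrid(1)
  # single location, single test: likelihood equals that level's log density
  s1 <- vfSeries(0, matrix(25, 1, 1), g1)
  ll <- seriesLogLikelihood(s1, slopes = 0, intercepts = 25, rm)
  expect_equal(ll, as.numeric(retestLogDensity(rm, 25, 25)), tolerance = 1e-12)
  # factorisation: two tests = sum of one-test likelihoods at fixed weights
  s2 <- vfSeries(c(0, 1), matrix(c(25, 23), 2, 1), g1)
  sa <- vfSeries(0, matrix(25, 1, 1), g1)
  sb <- vfSeries(1, matrix(23, 1, 1), g1)
  w <- list(slopes = -0.7, intercepts = 25.2)
  expect_equal(seriesLogLikelihood(s2, w$slopes, w$intercepts, rm),
               seriesLogLikelihood(sa, w$slopes, w$intercepts, rm) +
                 seriesLogLikelihood(sb, w$slopes, w$intercepts, rm),
               tolerance = 1e-12)
})

test_that("with a diagonal prior the log posterior decomposes per location", {
  rm <- toyRetestModel()
  g <- toyGrid(2)
  pr <- dropSpatial(buildSpatialPrior(g))
  s <- toySeries(matrix(c(30, 29, 28, 20, 21, 19), ncol = 2))
  sl <- c(-0.5, 0.3); ic <- c(30, 20)
  lp <- seriesLogPosterior(s, sl, ic, rm, pr)
  perLoc <- vapply(1:2, function(j) {
    sj <- vfSeries(s@times, s@values[, j, drop = FALSE], toyGrid(1))
    prj <- dropSpatial(buildSpatialPrior(toyGrid(1)))
    seriesLogPosterior(sj, sl[j], ic[j], rm, prj)
  }, numeric(1))
  expect_equal(lp, sum(perLoc), tolerance = 1e-8)
})

test_that("with an empty series the posterior peaks at the prior means", {
  rm <- toyRetestModel()
  g <- toyGrid(2)
  pr <- buildSpatialPrior(g)
  s0 <- vfSeries(numeric(0), matrix(numeric(0), 0, 2), g)
  atMean <- seriesLogPosterior(s0, rep(0, 2), rep(17.5, 2), rm, pr)
  for (k in 1:10) {
    d <- withr::with_seed(k, rnorm(4))
    expect_lt(seriesLogPosterior(s0, d[1:2], 17.5 + d[3:4], rm, pr), atMean)
  }
})

test_that("the analytic gradient matches central finite differences", {
  rm <- packagedRetestModel()
  g <- toyGrid(3)
  pr <- buildSpatialPrior(g)
  s <- toySeries(withr::with_seed(5, matrix(round(runif(12, 15, 33)), 4, 3)))
  obj <- posteriorObjective(s, rm, pr)
  p0 <- withr::with_seed(6, c(rnorm(3, 0, 0.5), rnorm(3, 25, 3)))
  gan <- obj$gr(p0)
  gfd <- vapply(seq_along(p0), function(k) {
    e <- rep(0, length(p0)); e[k] <- 1e-5
    (obj$fn(p0 + e) - obj$fn(p0 - e)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(gan - gfd)) / max(abs(gfd)), 1e-4)
})

test_that("MAP matches an exhaustive grid search on a 2-location toy", {
  rm <- toyRetestModel()
  g <- toyGrid(2)
  pr <- buildSpatialPrior(g)
  s <- toySeries(matrix(c(30, 28, 27, 25, 22, 21, 20, 18), ncol = 2))
  fit <- mapEstimate(s, rm, pr)
  # brute-force oracle: coarse 4-D lattice around plausible values, refined
  # twice around the incumbent
  obj <- posteriorObjective(s, rm, pr)
  centers <- c(-2, -2, 29, 22)
  widths <- c(3, 3, 5, 5)
  for (r in 1:3) {
    gr <- expand.grid(s1 = seq(centers[1] - widths[1], centers[1] + widths[1],
                               length.out = 9),
                      s2 = seq(centers[2] - widths[2], centers[2] + widths[2],
                               length.out = 9),
                      i1 = seq(centers[3] - widths[3], centers[3] + widths[3],
                               length.out = 9),
                      i2 = seq(centers[4] - widths[4], centers[4] + widths[4],
                               length.out = 9))
    vals <- apply(gr, 1, function(p) obj$fn(as.numeric(p)))
    centers <- as.numeric(gr[which.max(vals), ])
    widths <- widths / 4
  }
  step <- max(widths * 2 / 8)
  expect_lt(max(abs(c(fit$slopes, fit$intercepts) - centers)), 2 * step)
  expect_gte(fit$logPosterior, max(vals) - 1e-6)
})

test_that("in the prior-dominated limit the MAP returns the prior means", {
  rm <- toyRetestModel()
  g <- toyGrid(2)
  pr <- buildSpatialPrior(g, slopeSD = 1e-4, interceptSD = 1e-4,
                          interceptMean = 20)
  s <- toySeries(matrix(c(30, 28, 27, 25, 22, 21, 20, 18), ncol = 2))
  fit <- mapEstimate(s, rm, pr)
  expect_lt(max(abs(fit$slopes)), 1e-3)
  expect_lt(max(abs(fit$intercepts - 20)), 1e-3)
})

test_that("with no data the Laplace covariance equals the prior covariance", {
  rm <- toyRetestModel()
  g <- toyGrid(2)
  pr <- buildSpatialPrior(g)
  s0 <- vfSeries(numeric(0), matrix(numeric(0), 0, 2), g)
  cov <- laplaceCovariance(s0, rep(0, 2), rep(17.5, 2), rm, pr)
  expect_equal(cov[1:2, 1:2], pr@a * psi(pr), tolerance = 1e-4)
  expect_equal(cov[3:4, 3:4], pr@b * psi(pr), tolerance = 1e-4)
  expect_equal(cov[1:2, 3:4], matrix(0, 2, 2), tolerance = 1e-6)
  expect_equal(cov, t(cov))
  expect_true(all(diag(cov) > 0))
})

test_that("Laplace slope variance agrees with a quadrature oracle on a 1-location toy", {
  # tight measurement model: the posterior is close to Gaussian, where the
  # Laplace approximation should be accurate (with broad mixtures the true
  # posterior is heavy-tailed and the Laplace variance is known to
  # underestimate it)
  rm <- toyRetestModel(shape = 30)
  g1 <- toyGrid(1)
  pr <- dropSpatial(buildSpatialPrior(g1))
  s <- vfSeries(0:4, matrix(c(30, 29, 27, 28, 25), 5, 1), g1)
  fit <- mapEstimate(s, rm, pr)
  cov <- laplaceCovariance(s, fit$slopes, fit$intercepts, rm, pr)
  prec <- solve(cov)                    # conditional variance of the slope
  condVar <- 1 / prec[1, 1]
  # oracle: 1-D quadrature over the slope with the intercept fixed at the
  # mode -> compare against the conditional Laplace variance 1 / (-H_ss)
  obj <- posteriorObjective(s, rm, pr)
  f <- Vectorize(function(sl) exp(obj$fn(c(sl, fit$intercepts)) -
                                    fit$logPosterior))
  w <- 8 * sqrt(condVar)
  z0 <- stats::integrate(f, fit$slopes - w, fit$slopes + w)$value
  m1 <- stats::integrate(function(x) x * f(x), fit$slopes - w,
                         fit$slopes + w)$value / z0
  v <- stats::integrate(function(x) (x - m1)^2 * f(x), fit$slopes - w,
                        fit$slopes + w)$value / z0
  expect_lt(abs(condVar - v) / v, 0.2)
})

test_that("Pnd follows the closed-form normal probabilities", {
  expect_equal(pndFromSlope(0, 1), 0.5)
  expect_equal(pndFromSlope(-3, 1), pnorm(-3), tolerance = 1e-12)
  expect_equal(pndFromSlope(-3 * 0.4, 0.4), pnorm(-3), tolerance = 1e-12)
  expect_equal(pndFromSlope(1e6, 1), 1)
  expect_equal(pndFromSlope(-1e6, 1), 1e-300)
})

test_that("the deterioration index is additive and permutation invariant", {
  expect_equal(sIndex(rep(1, 10)), 0)
  expect_equal(sIndex(c(0.1, 1, 1)), -log(0.1), tolerance = 1e-12)
  u <- c(0.3, 0.9, 0.5); v <- c(0.99, 0.2)
  expect_equal(sIndex(c(u, v)), sIndex(u) + sIndex(v), tolerance = 1e-12)
  p <- withr::with_seed(3, runif(20, 0.01, 1))
  expect_equal(sIndex(p), sIndex(sample(p)), tolerance = 1e-12)
  expect_warning(sIndex(c(0.5, 0)), "clamped")
})

test_that("analyzeSeries is deterministic and symmetric under improvement", {
  rm <- packagedRetestModel()
  g <- fullGrid()
  pr <- fullPrior()
  cohort <- genCohort(generatorConfig(nEyes = 1, propProgressing = 0,
                                      seed = 21), g)
  s <- cohort$series[[1]]
  e1 <- analyzeSeries(s, rm, pr)
  e2 <- analyzeSeries(s, rm, pr)
  expect_identical(deteriorationIndex(e1), deteriorationIndex(e2))
  # uniform improvement: improvement index exceeds deterioration index
  up <- pmin(sweep(s@values, 1, 2 * s@times, "+"), 36)
  sUp <- vfSeries(s@times, up, g, "up")
  eUp <- analyzeSeries(sUp, rm, pr)
  expect_gt(improvementIndex(eUp), deteriorationIndex(eUp))
})

test_that("ANSWER equals ANSWERS when the prior has no off-diagonal coupling", {
  rm <- toyRetestModel()
  g <- toyGrid(3)
  prDiag <- dropSpatial(buildSpatialPrior(g))
  vals <- withr::with_seed(31, matrix(round(runif(15, 18, 33)), 5, 3))
  s <- toySeries(vals)
  eS <- analyzeSeries(s, rm, prDiag, mode = "ANSWERS")
  eA <- analyzeSeries(s, rm, prDiag, mode = "ANSWER")
  expect_lt(abs(deteriorationIndex(eS) - deteriorationIndex(eA)), 1e-9)
})

test_that("the deterioration index is invariant to a consistent location permutation", {
  rm <- packagedRetestModel()
  g <- fullGrid()
  pr <- fullPrior()
  cohort <- genCohort(generatorConfig(nEyes = 1, propProgressing = 1,
                                      seed = 41), g)
  s <- cohort$series[[1]]
  e0 <- analyzeSeries(s, rm, pr)
  perm <- withr::with_seed(42, sample(52))
  loc <- locations(g)[perm, ]
  loc$index <- seq_len(52) - 1L
  gPerm <- new("VisualFieldGrid", locations = loc,
               adjacency = adjacency(g)[perm, perm], eye = "right")
  sPerm <- vfSeries(s@times, s@values[, perm], gPerm, s@eyeId)
  prPerm <- buildSpatialPrior(gPerm)
  ePerm <- analyzeSeries(sPerm, rm, prPerm)
  expect_equal(deteriorationIndex(ePerm), deteriorationIndex(e0),
               tolerance = 1e-6)
  expect_equal(slopes(ePerm), slopes(e0)[perm], tolerance = 1e-4)
})
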