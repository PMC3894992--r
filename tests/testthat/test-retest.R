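test_that("the packaged fitted retest model is valid and integrates to 1 at every level", {
  m <- packagedRetestModel()
  expect_s4_class(m, "RetestModel")
  expect_equal(m@levels, 0:35)
  for (i in seq_along(m@levels)) {
    mx <- weibullMixture(m@weights[i, ], m@alphas[i, ], m@betas[i, ])
    I <- stats::integrate(function(x) dweibullMixture(x, mx), 0, 2,
                          rel.tol = 1e-9)$value +
      stats::integrate(function(x) dweibullMixture(x, mx), 2, 400,
                       rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
})

test_that("the interpolated log density is continuous with bounded differences in mu", {
  m <- packagedRetestModel()
  mus <- seq(0, 35, by = 0.01)
  # the floor level (y = 0) sits on the censoring spike, whose weight decays
  # quickly in mu, so its slope bound is looser
  bound <- c("0" = 6, "7" = 0.7, "21" = 0.7, "33" = 0.7)
  for (y in c(0, 7, 21, 33)) {
    ld <- retestLogDensity(m, y, mus)
    expect_true(all(is.finite(ld)))
    expect_lt(max(abs(diff(ld))), bound[[as.character(y)]])
  }
})

test_that("the fitted retest interval widens as sensitivity falls", {
  m <- packagedRetestModel()
  w <- vapply(c(32, 26, 20), function(v) diff(retestQuantiles(m, v)),
              numeric(1))
  expect_lt(w[1], w[2])
  expect_lt(w[2], w[3])
})

test_that("fitRetestModel pools sparse levels and carries the selected K", {
  # small synthetic pair set; K fixed for speed
  pairs <- genRetestPairs(generatorConfig(nEyes = 6, nRepeats = 6, seed = 4))
  m <- suppressWarnings(
    fitRetestModel(pairs, K = 2, minPerLevel = 40, maxPerLevel = 300,
                   seed = 2))
  expect_equal(m@K, 2L)
  expect_true(is.na(m@selectedK))
  expect_true(all(rowSums(m@weights) - 1 < 1e-8))
  expect_true(all(m@alphas > 0 & m@betas > 0))
})

test_that("retest model serialisation round-trips exactly", {
  m <- packagedRetestModel()
  f <- tempfile(fileext = ".json")
  writeRetestModel(m, f)
  m2 <- readRetestModel(f)
  expect_equal(m2@weights, m@weights)
  expect_equal(m2@alphas, m@alphas)
  expect_equal(m2@betas, m@betas)
  expect_equal(m2@levels, m@levels)
  expect_equal(m2@transformKnot, m@transformKnot)
})

test_that("the mixture density matches Monte-Carlo sampling of its own components", {
  m <- packagedRetestModel()
  i <- match(20, m@levels)
  mx <- weibullMixture(m@weights[i, ], m@alphas[i, ], m@betas[i, ])
  n <- 20000
  draws <- withr::with_seed(55, {
    comp <- sample.int(length(mx$weights), n, replace = TRUE,
                       prob = mx$weights)
    rweibull(n, shape = mx$alphas[comp], scale = mx$betas[comp])
  })
  for (win in list(c(5, 15), c(15, 25), c(25, 33))) {
    pHat <- mean(draws >= win[1] & draws < win[2])
    pMod <- stats::integrate(function(x) dweibullMixture(x, mx),
                             win[1], win[2], rel.tol = 1e-9)$value
    se <- sqrt(pMod * (1 - pMod) / n)
    expect_lt(abs(pHat - pMod), 3 * se + 1e-6)
  }
})
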