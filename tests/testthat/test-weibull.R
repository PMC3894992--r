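test_that("the Weibull mixture density matches special cases and integrates to 1", {
  # exponential special case
  expect_equal(dweibullMixture(1, weibullMixture(1, 1, 1)), exp(-1),
               tolerance = 1e-12)
  # shape > 1 vanishes at the origin
  expect_equal(dweibullMixture(0, weibullMixture(1, 2, 5)), 0)
  # domain error below 0
  expect_error(dweibullMixture(-1, weibullMixture(1, 2, 5)), "non-negative")
  # unit mass by quadrature
  mx <- weibullMixture(c(0.4, 0.6), c(2, 6), c(10, 25))
  I <- stats::integrate(function(x) dweibullMixture(x, mx), 0, 200,
                        rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-6)
})

test_that("the low-end sensitivity transform is positive, continuous and C1", {
  expect_equal(transformDls(20), 20)
  expect_equal(transformDls(1), 1)
  expect_equal(transformDls(0), exp(-1), tolerance = 1e-12)
  expect_error(transformDls(-0.5), "non-negative")
  # value and derivative agree at the knot
  h <- 1e-7
  left <- (transformDls(1) - transformDls(1 - h)) / h
  right <- (transformDls(1 + h) - transformDls(1)) / h
  expect_equal(left, 1, tolerance = 1e-5)
  expect_equal(right, 1, tolerance = 1e-5)
  expect_true(all(transformDls(seq(0, 35, by = 0.1)) > 0))
})

test_that("EM recovers single-Weibull parameters against a grid-search oracle", {
  y <- withr::with_seed(101, rweibull(5000, shape = 3, scale = 20))
  fit <- emFitWeibullMixture(y, K = 1)
  # independent oracle: dense grid search over (shape, scale)
  grid <- expand.grid(a = seq(2.0, 4.0, by = 0.02),
                      b = seq(18, 22, by = 0.02))
  ll <- mapply(function(a, b) sum(dweibull(y, a, b, log = TRUE)),
               grid$a, grid$b)
  best <- grid[which.max(ll), ]
  expect_equal(fit$mixture$alphas, best$a, tolerance = 0.02)
  expect_equal(fit$mixture$betas, best$b, tolerance = 0.02)
  # and within the stated tolerance of the truth
  expect_lt(abs(fit$mixture$alphas - 3) / 3, 0.05)
  expect_lt(abs(fit$mixture$betas - 20) / 20, 0.02)
})

test_that("EM log-likelihood ascends monotonically on every seed", {
  for (s in 1:5) {
    y <- withr::with_seed(200 + s, c(rweibull(600, 5, 25),
                                     rweibull(400, 1.5, 5)))
    fit <- emFitWeibullMixture(y, K = 2, seed = s)
    expect_true(all(diff(fit$trace) >= -1e-9))
  }
})

test_that("EM recovers two-component mixture weights within 0.05", {
  y <- withr::with_seed(77, c(rweibull(3500, 5, 25), rweibull(1500, 1.5, 5)))
  fit <- emFitWeibullMixture(y, K = 2)
  w <- sort(fit$mixture$weights)
  expect_lt(max(abs(w - c(0.3, 0.7))), 0.05)
})

test_that("cross-validated component selection finds the generating K", {
  # clearly bimodal two-component data
  y2 <- withr::with_seed(11, c(rweibull(1400, 6, 25), rweibull(600, 1.5, 4)))
  expect_equal(selectComponentCount(y2, seed = 1), 2L)
  # single-component data
  y1 <- withr::with_seed(12, rweibull(2000, 3, 20))
  expect_equal(selectComponentCount(y1, seed = 1), 1L)
  # no alternative considered
  expect_equal(selectComponentCount(y1, kMax = 1), 1L)
})
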