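test_that("OLS matches a normal-equations oracle and handles degenerate input", {
  # noiseless line
  t5 <- 0:4
  fit <- olsFit(t5, 30 - 1.5 * t5)
  expect_equal(fit$slope, -1.5, tolerance = 1e-10)
  expect_lt(fit$p, 1e-6)
  # constant series policy
  fc <- olsFit(t5, rep(12, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$p, 1)
  # degenerate design
  expect_error(olsFit(rep(1, 4), 1:4), "degenerate")
  # seeded noisy series against an independent normal-equations oracle
  for (s in 1:5) {
    y <- withr::with_seed(s, 28 - 0.8 * t5 + rnorm(5))
    fit <- olsFit(t5, y)
    X <- cbind(1, t5)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    se <- sqrt(sum(res^2) / 3 * solve(t(X) %*% X)[2, 2])
    p <- 2 * pt(-abs(beta[2] / se), df = 3)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$p, p, tolerance = 1e-10)
  }
})

test_that("mean-deviation regression behaves as a global summary", {
  g <- fullGrid()
  normative <- healthyMeans(g)
  t5 <- 0:4
  # series equal to the normative field: zero mean deviation, no call
  vals <- matrix(normative, 5, 52, byrow = TRUE)
  s <- vfSeries(t5, vals, g)
  r <- mdRegression(s, normative)
  expect_equal(r$mdSeries, rep(0, 5))
  expect_false(r$deteriorating)
  # uniform decline of 1 dB/year shows up exactly in the summary slope
  vals2 <- vals - outer(t5, rep(1, 52))
  r2 <- mdRegression(vfSeries(t5, vals2, g), normative)
  expect_equal(r2$slope, -1, tolerance = 1e-10)
  expect_true(r2$deteriorating)
  # decline confined to 1 of 52 locations dilutes to slope -2/52
  vals3 <- vals
  vals3[, 7] <- vals3[, 7] - 2 * t5
  r3 <- mdRegression(vfSeries(t5, vals3, g), normative)
  expect_equal(r3$slope, -2 / 52, tolerance = 1e-10)
  expect_error(mdRegression(s, NULL), "normative")
})

test_that("point-wise linear regression applies hemifield-restricted contiguity", {
  g <- fullGrid()
  normative <- healthyMeans(g)
  t5 <- 0:4
  vals <- matrix(normative, 5, 52, byrow = TRUE)
  loc <- locations(g)
  adj <- adjacency(g)
  # three contiguous superior locations declining steeply, noiseless
  sup <- which(loc$hemifield == "superior")
  seedLoc <- sup[which.max(rowSums(adj[sup, sup]))]
  nb <- intersect(which(adj[seedLoc, ]), sup)[1]
  nb2 <- setdiff(intersect(which(adj[nb, ]), sup), c(seedLoc, nb))[1]
  cl3 <- c(seedLoc, nb, nb2)
  v <- vals; v[, cl3] <- v[, cl3] - 3 * t5
  r <- plr(vfSeries(t5, v, g))
  expect_true(all(r$deteriorating[cl3]))
  expect_true(r$decision[["n2"]])
  expect_true(r$decision[["n3"]])
  expect_false(r$decision[["n4"]])
  # two deteriorating locations adjacent across the midline do not join
  pairUp <- which(loc$y_deg == 3 & loc$x_deg == -3)
  pairDn <- which(loc$y_deg == -3 & loc$x_deg == -3)
  stopifnot(adj[pairUp, pairDn])
  v2 <- vals; v2[, c(pairUp, pairDn)] <- v2[, c(pairUp, pairDn)] - 3 * t5
  r2 <- plr(vfSeries(t5, v2, g))
  expect_true(all(r2$deteriorating[c(pairUp, pairDn)]))
  expect_false(r2$decision[["n2"]])
  expect_true(r2$decision[["n1"]])
  # with midline-crossing contiguity they do join
  r3 <- plr(vfSeries(t5, v2, g), contiguity = "4")
  expect_true(r3$decision[["n2"]])
  # stable noiseless series: no call at any criterion
  r0 <- plr(vfSeries(t5, vals, g))
  expect_false(any(r0$decision))
})

test_that("the contiguity decision is monotone non-increasing in n", {
  g <- fullGrid()
  for (s in 1:5) {
    cohort <- genCohort(generatorConfig(nEyes = 1, propProgressing = 1,
                                        clusterSize = 8,
                                        progressionSlope = -3,
                                        seed = 500 + s), g)
    r <- plr(cohort$series[[1]])
    expect_true(all(diff(r$decision) <= 0))
  }
})
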