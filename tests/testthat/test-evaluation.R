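test_that("pseudo-series sets have the prescribed combinatorial size", {
  rr <- genRetestRepeats(generatorConfig(nEyes = 4, nRepeats = 8, seed = 3))
  set <- makePseudoSeries(rr, nReorder = 10, lengths = 3:8, seed = 1)
  expect_equal(countPseudoSeries(set), 4 * 10 * 6)
  # identity reordering reproduces the original order
  setId <- makePseudoSeries(rr, nReorder = 1, lengths = 8, seed = 1,
                            identityFirst = TRUE)
  s <- getPseudoSeries(setId, 1)
  expect_equal(s@values, rr$repeats[[1]][1:8, ])
  expect_equal(s@times, 0:7)
  # requesting more repeats than available fails
  expect_error(makePseudoSeries(rr, nReorder = 2, lengths = 3:9), "exceeds")
})

test_that("false positive rate estimates come with exact binomial intervals", {
  expect_equal(fprEstimate(rep(FALSE, 50))$rate, 0)
  expect_equal(fprEstimate(rep(TRUE, 50))$rate, 1)
  dec <- withr::with_seed(8, runif(10000) < 0.5)
  est <- fprEstimate(dec)
  expect_lt(abs(est$rate - 0.5), 0.015)
  expect_lt(est$ci[1], 0.5)
  expect_gt(est$ci[2], 0.5)
})

test_that("threshold selection matches order statistics of the null scores", {
  sc <- withr::with_seed(13, runif(10000))
  thr <- thresholdAtFpr(sc, 0.05)
  expect_lt(abs(thr - 0.95), 0.01)
  achieved <- mean(sc > thr)
  expect_lte(achieved, 0.05)
  expect_gte(achieved, 0.05 - 1 / length(sc))
  # limit cases
  expect_equal(thresholdAtFpr(sc, 0), max(sc))
  expect_error(thresholdAtFpr(sc, 1e-6), "resolution")
  expect_error(thresholdAtFpr(runif(50), 0.1), "at least 100")
})

test_that("time to detect returns the span of the first flagged prefix", {
  g <- toyGrid(2)
  s <- vfSeries(c(0, 1.5, 2.5, 4, 5.5),
                matrix(30, 5, 2), g)
  # detector flagging exactly at prefix length k, for every k
  for (k in 3:5) {
    det <- function(prefix) length(prefix@times) >= k
    expect_equal(timeToDetect(s, det), s@times[k] - s@times[1])
  }
  # never flagged: total span
  expect_equal(timeToDetect(s, function(prefix) FALSE),
               s@times[5] - s@times[1])
  # failing detector counts as not flagged
  expect_equal(
    suppressMessages(timeToDetect(s, function(prefix) stop("boom"))),
    s@times[5] - s@times[1])
})

test_that("normalised partial AUC has the stated anchor values", {
  f <- seq(0, 0.15, by = 0.005)
  # perfect detector
  expect_equal(partialAuc(f, rep(1, length(f))), 1)
  # hit rate equal to the FPR (useless detector on a fully stable cohort):
  # the triangle has raw area 0.15^2 / 2, normalised by 0.15
  expect_equal(partialAuc(f, f), 0.15 / 2, tolerance = 1e-12)
  # grid must cover [0, 0.15]
  expect_error(partialAuc(seq(0.02, 0.15, by = 0.005), rep(1, 27)), "cover")
})

test_that("a perfect detector reproduces the hit-rate mixture identity", {
  # cohort with known progressing fraction p: a perfect detector flags all
  # progressing series plus a fraction FPR of the stable ones
  p <- 0.3; fpr <- 0.06; n <- 5000
  progressing <- withr::with_seed(17, runif(n) < p)
  flags <- progressing |
    withr::with_seed(18, runif(n)) < fpr
  expect_equal(hitRate(flags),
               p + (1 - p) * fpr,
               tolerance = 0.02)
})

test_that("evaluationReport calibrates thresholds and integrates the curve", {
  nullSc <- withr::with_seed(19, runif(2000))
  cohortSc <- withr::with_seed(20, c(runif(300), runif(700, 0.5, 1.5)))
  rep <- evaluationReport(nullSc, cohortSc)
  expect_true(all(rep$curve$achieved_fpr <= rep$curve$target_fpr + 1e-12))
  expect_true(all(diff(rep$curve$threshold) <= 0))
  expect_true(all(diff(rep$curve$hit_rate) >= 0))
  # better than the chance diagonal, and self-consistent with the curve
  expect_gt(rep$partialAuc, partialAuc(rep$curve$target_fpr,
                                       rep$curve$target_fpr))
  expect_lte(rep$partialAuc, 1)
  expect_equal(rep$partialAuc,
               partialAuc(rep$curve$target_fpr, rep$curve$hit_rate))
})
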