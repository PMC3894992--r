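# Synthetic data generator: test-retest repeats/pairs and progressing
# cohorts with the statistical structure of perimetric measurements
# (per-level skewed/bimodal retest scatter that widens as sensitivity falls,
# censoring at 0 dB, spatially contiguous within-hemifield progression).

#' Configuration for the synthetic data generator
#'
#' Defaults emulate the study conditions: 30 eyes tested 12 times for the
#' retest data; yearly tests; a 30% progressing cohort losing 1 dB/year in a
#' cluster of 6 contiguous same-hemifield locations. The noise model is a
#' two-component mixture per true level: a "reliable" component centred on
#' the true level whose spread widens as the level falls (about a 7 dB 90%
#' retest range at 32 dB and 18 dB at 20 dB), plus a low-sensitivity "lapse"
#' component producing the characteristic heavy low tail; values are rounded
#' to integer dB and censored at 0.
#'
#' @param nEyes,nRepeats retest design (eyes, repeats per eye).
#' @param nTests,intervalYears cohort series design.
#' @param propProgressing proportion of progressing eyes in a cohort.
#' @param clusterSize number of contiguous locations that progress.
#' @param progressionSlope true slope at progressing locations (dB/year).
#' @param onsetYears progression onset time.
#' @param lapseWeightMax lapse-component weight at 0 dB; the weight falls
#'   linearly to 0 at 35 dB, so healthy levels are nearly lapse-free while
#'   damaged levels show the characteristic bimodal low tail.
#' @param sdFloor,sdSlope reliable-component SD: `sdFloor + sdSlope * (33 - level)`.
#' @param lapseShape,lapseScaleFrac,lapseScaleMin lapse-component Weibull
#'   shape and scale (`max(lapseScaleMin, lapseScaleFrac * level)`).
#' @param damageProb,damageShape,damageScale per-location glaucomatous
#'   damage in the retest eyes (Bernoulli-gamma, dB).
#' @param eyeSd,locSd between-eye and between-location SD of the baseline
#'   profile (dB), shared by the retest and cohort generators so both
#'   sample the same true-level population.
#' @param maxDb ceiling of generated sensitivities (soft instrument
#'   ceiling; healthy measurements rarely print above 36 dB).
#' @param seed RNG seed.
#' @return a list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(nEyes = 30, nRepeats = 12, nTests = 7,
                            intervalYears = 1, propProgressing = 0.3,
                            clusterSize = 6, progressionSlope = -1,
                            onsetYears = 0, lapseWeightMax = 0.15,
                            sdFloor = 1.0, sdSlope = 0.25,
                            lapseShape = 1.3, lapseScaleFrac = 0.4,
                            lapseScaleMin = 2, damageProb = 0.45,
                            damageShape = 1.1, damageScale = 14,
                            eyeSd = 1.5, locSd = 0.7,
                            maxDb = 36, seed = 1) {
  structure(as.list(environment()), class = "GeneratorConfig")
}

#' Healthy mean sensitivity profile for a grid
#'
#' A simple eccentricity fall-off: about 33 dB centrally, dropping 0.22
#' dB per degree of eccentricity.
#'
#' @param grid a \linkS4class{VisualFieldGrid}.
#' @return per-location means (dB).
#' @export
healthyMeans <- function(grid) {
  loc <- locations(grid)
  34 - 0.22 * sqrt(loc$x_deg^2 + loc$y_deg^2)
}

# Vectorised Weibull shape for a target coefficient of variation, via a
# log-log interpolation table of cv(shape).
.shapeForCv <- local({
  tab <- NULL
  function(cv) {
    if (is.null(tab)) {
      sh <- exp(seq(log(0.15), log(500), length.out = 500))
      cvs <- sqrt(gamma(1 + 2 / sh) / gamma(1 + 1 / sh)^2 - 1)
      tab <<- list(lcv = rev(log(cvs)), lsh = rev(log(sh)))
    }
    lcv <- pmin(pmax(log(cv), min(tab$lcv)), max(tab$lcv))
    exp(stats::approx(tab$lcv, tab$lsh, xout = lcv)$y)
  }
})

# One noisy measurement per entry of `mu` (true levels, dB).
.drawNoisy <- function(mu, cfg) {
  n <- length(mu)
  mReliable <- pmax(mu, 0.6)
  sdRel <- cfg$sdFloor + cfg$sdSlope * pmax(33 - mu, 0)
  shapeRel <- .shapeForCv(sdRel / mReliable)
  scaleRel <- mReliable / gamma(1 + 1 / shapeRel)
  wLapse <- cfg$lapseWeightMax * pmax(1 - mu / 35, 0)
  lapse <- stats::runif(n) < wLapse
  shape <- ifelse(lapse, cfg$lapseShape, shapeRel)
  scale <- ifelse(lapse, pmax(cfg$lapseScaleMin, cfg$lapseScaleFrac * mu),
                  scaleRel)
  draw <- stats::rweibull(n, shape = shape, scale = scale)
  pmin(pmax(round(draw), 0), cfg$maxDb)
}

#' Generate synthetic test-retest repeat matrices
#'
#' Each eye gets a fixed true sensitivity profile (healthy means minus
#' Bernoulli-gamma glaucomatous damage, covering the full 0-35 dB range over
#' the cohort) and `nRepeats` independent noisy measurements of it.
#'
#' @param config a [generatorConfig()].
#' @param grid a \linkS4class{VisualFieldGrid}.
#' @return list with `repeats` (per eye, an nRepeats x M matrix),
#'   `trueLevels` (nEyes x M) and `grid`.
#' @export
genRetestRepeats <- function(config, grid = buildGrid()) {
  m <- nLocations(grid)
  hm <- healthyMeans(grid)
  .withSeed(config$seed, {
    repeats <- vector("list", config$nEyes)
    trueLevels <- matrix(0, config$nEyes, m)
    for (e in seq_len(config$nEyes)) {
      damage <- stats::rbinom(m, 1, config$damageProb) *
        stats::rgamma(m, shape = config$damageShape,
                      scale = config$damageScale)
      lv <- pmin(pmax(hm + stats::rnorm(1, 0, config$eyeSd) +
                        stats::rnorm(m, 0, config$locSd) - damage, 0), 35)
      trueLevels[e, ] <- lv
      repeats[[e]] <- matrix(
        .drawNoisy(rep(lv, each = config$nRepeats), config),
        nrow = config$nRepeats)
    }
    list(repeats = repeats, trueLevels = trueLevels, grid = grid)
  })
}

#' Test-retest pairs from repeat matrices
#'
#' Emits all unordered pairs of repeats per eye: for `nEyes` eyes with `R`
#' repeats each, `nEyes * choose(R, 2)` test pairs (each carrying all M
#' locations).
#'
#' @param repeats list of repeat matrices (one per eye), or the result of
#'   [genRetestRepeats()].
#' @return data.frame with columns `eye_id`, `test_a_index`, `test_b_index`,
#'   `location_index`, `baseline_dls`, `retest_dls`.
#' @export
retestPairsFromRepeats <- function(repeats) {
  if (is.list(repeats) && !is.null(repeats$repeats))
    repeats <- repeats$repeats
  out <- lapply(seq_along(repeats), function(e) {
    rm <- repeats[[e]]
    m <- ncol(rm)
    cmb <- utils::combn(nrow(rm), 2)
    data.frame(
      eye_id = sprintf("eye_%02d", e),
      test_a_index = rep(cmb[1, ], each = m),
      test_b_index = rep(cmb[2, ], each = m),
      location_index = rep(0:(m - 1), times = ncol(cmb)),
      baseline_dls = as.vector(t(rm[cmb[1, ], , drop = FALSE])),
      retest_dls = as.vector(t(rm[cmb[2, ], , drop = FALSE])))
  })
  do.call(rbind, out)
}

#' Number of distinct test pairs in a pairs table
#' @param pairs result of [retestPairsFromRepeats()].
#' @return count of distinct (eye, test pair) combinations.
#' @export
countRetestPairs <- function(pairs)
  nrow(unique(pairs[, c("eye_id", "test_a_index", "test_b_index")]))

#' Generate synthetic test-retest pairs
#'
#' [genRetestRepeats()] followed by [retestPairsFromRepeats()].
#'
#' @inheritParams genRetestRepeats
#' @return a pairs data.frame (see [retestPairsFromRepeats()]).
#' @export
genRetestPairs <- function(config, grid = buildGrid())
  retestPairsFromRepeats(genRetestRepeats(config, grid))

# Grow a connected within-hemifield cluster from a seed location.
.growCluster <- function(grid, seedLoc, size) {
  adj <- adjacency(grid)
  hemi <- locations(grid)$hemifield
  adj <- adj & outer(hemi, hemi, "==")
  cl <- seedLoc
  while (length(cl) < size) {
    frontier <- setdiff(which(apply(adj[cl, , drop = FALSE], 2, any)), cl)
    if (!length(frontier))
      stop("cannot grow a connected cluster of size ", size,
           " from location ", seedLoc - 1)
    cl <- c(cl, frontier[sample.int(length(frontier), 1)])
  }
  cl
}

#' Generate a synthetic cohort of visual-field series with ground truth
#'
#' Stable eyes carry a constant true field plus measurement noise;
#' progressing eyes decline linearly at a cluster of contiguous
#' same-hemifield locations from the onset time.
#'
#' @inheritParams genRetestRepeats
#' @return list with `series` (list of \linkS4class{VFSeries}), `progressing`
#'   (logical labels), `trueSlopes` (nEyes x M) and `clusters` (per-eye
#'   0-based location indices, NULL for stable eyes).
#' @export
genCohort <- function(config, grid = buildGrid()) {
  m <- nLocations(grid)
  hm <- healthyMeans(grid)
  times <- (seq_len(config$nTests) - 1) * config$intervalYears
  .withSeed(config$seed, {
    nProg <- round(config$nEyes * config$propProgressing)
    progressing <- rep(FALSE, config$nEyes)
    if (nProg > 0) progressing[sample.int(config$nEyes, nProg)] <- TRUE
    series <- vector("list", config$nEyes)
    trueSlopes <- matrix(0, config$nEyes, m)
    clusters <- vector("list", config$nEyes)
    for (e in seq_len(config$nEyes)) {
      base <- pmin(pmax(hm + stats::rnorm(1, 0, config$eyeSd) +
                          stats::rnorm(m, 0, config$locSd), 5), 35)
      sl <- rep(0, m)
      if (progressing[e]) {
        cl <- .growCluster(grid, sample.int(m, 1), config$clusterSize)
        sl[cl] <- config$progressionSlope
        clusters[[e]] <- cl - 1L
      }
      truth <- outer(pmax(times - config$onsetYears, 0), sl) +
        matrix(base, length(times), m, byrow = TRUE)
      truth <- pmin(pmax(truth, 0), 38)
      vals <- matrix(.drawNoisy(as.vector(truth), config),
                     nrow = length(times))
      series[[e]] <- vfSeries(times, vals, grid,
                              eyeId = sprintf("sim_%03d", e))
      trueSlopes[e, ] <- sl
    }
    list(series = series, progressing = progressing,
         trueSlopes = trueSlopes, clusters = clusters)
  })
}
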