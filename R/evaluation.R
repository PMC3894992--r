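# False-positive-calibrated evaluation protocol: reordered pseudo-series,
# empirical thresholds at target false-positive rates, time-to-detect, hit
# rate and normalised partial AUC.

#' Build reordered pseudo-series from test-retest repeats
#'
#' Each eye's repeats are randomly reordered `nReorder` times (permutations
#' sampled uniformly, distinct per eye); for every requested length L the
#' first L tests of a reordering form a stable pseudo-series, with an
#' assumed fixed test interval. For E eyes, R reorderings and lengths
#' Lmin..Lmax this yields `E * R * (Lmax - Lmin + 1)` pseudo-series; the
#' set is stored compactly (permutations + provenance) and individual
#' series are materialised on demand with [getPseudoSeries()].
#'
#' @param repeats list of per-eye repeat matrices, or [genRetestRepeats()]
#'   output.
#' @param nReorder reorderings per eye.
#' @param lengths pseudo-series lengths (each <= repeats per eye).
#' @param intervalYears assumed interval between tests (1 year).
#' @param seed RNG seed.
#' @param grid the \linkS4class{VisualFieldGrid}; taken from
#'   [genRetestRepeats()] output when available.
#' @param identityFirst force the first reordering of each eye to be the
#'   identity permutation.
#' @return a list of class `PseudoSeriesSet` with elements `permutations`,
#'   `provenance` (data.frame eye / reorder / length), `repeats`,
#'   `intervalYears`, `grid`.
#' @export
makePseudoSeries <- function(repeats, nReorder = 300, lengths = 3:12,
                             intervalYears = 1, seed = 1, grid = NULL,
                             identityFirst = FALSE) {
  if (is.list(repeats) && !is.null(repeats$repeats)) {
    if (is.null(grid)) grid <- repeats$grid
    repeats <- repeats$repeats
  }
  if (is.null(grid)) stop("a grid is required")
  nr <- vapply(repeats, nrow, integer(1))
  if (any(max(lengths) > nr))
    stop("requested length ", max(lengths),
         " exceeds the available repeats (", min(nr), ")")
  perms <- .withSeed(seed, lapply(seq_along(repeats), function(e) {
    n <- nr[e]
    seen <- character(0)
    out <- vector("list", nReorder)
    i <- 1L
    while (i <= nReorder) {
      p <- if (identityFirst && i == 1L) seq_len(n) else sample.int(n)
      key <- paste(p, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[i]] <- p
        i <- i + 1L
      }
    }
    out
  }))
  prov <- expand.grid(length = lengths, reorder = seq_len(nReorder),
                      eye = seq_along(repeats))[, c("eye", "reorder", "length")]
  structure(list(permutations = perms, provenance = prov, repeats = repeats,
                 intervalYears = intervalYears, grid = grid),
            class = "PseudoSeriesSet")
}

#' Number of pseudo-series in a set
#' @param set a [makePseudoSeries()] result.
#' @export
countPseudoSeries <- function(set) nrow(set$provenance)

#' Materialise one pseudo-series
#'
#' @param set a [makePseudoSeries()] result.
#' @param i row of `set$provenance`.
#' @return a \linkS4class{VFSeries} with times 0, interval, 2*interval, ...
#' @export
getPseudoSeries <- function(set, i) {
  pr <- set$provenance[i, ]
  p <- set$permutations[[pr$eye]][[pr$reorder]][seq_len(pr$length)]
  vfSeries((seq_len(pr$length) - 1) * set$intervalYears,
           set$repeats[[pr$eye]][p, , drop = FALSE], set$grid,
           eyeId = sprintf("pseudo_e%d_r%d_l%d", pr$eye, pr$reorder,
                           pr$length))
}

#' Score a subset of pseudo-series
#'
#' @param set a [makePseudoSeries()] result.
#' @param scorer function mapping a \linkS4class{VFSeries} to a numeric
#'   score (larger = more deterioration).
#' @param indices provenance rows to score (default: all).
#' @return numeric scores.
#' @export
scorePseudoSeries <- function(set, scorer, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(countPseudoSeries(set))
  vapply(indices, function(i) scorer(getPseudoSeries(set, i)), numeric(1))
}

#' False positive rate of a set of decisions
#'
#' @param decisions logical deterioration calls over stable (null) series.
#' @return list with `rate` and the exact binomial 95% `ci`.
#' @export
fprEstimate <- function(decisions) {
  stopifnot(length(decisions) > 0)
  bt <- stats::binom.test(sum(decisions), length(decisions))
  list(rate = mean(decisions), ci = as.numeric(bt$conf.int))
}

#' Decision threshold at a target false positive rate
#'
#' Empirical (1 - targetFpr) quantile of the null scores: flagging scores
#' strictly above the threshold achieves a false positive rate within one
#' rank of the target. `targetFpr = 0` returns the maximum null score.
#'
#' @param scores null (stable pseudo-series) scores, at least 100.
#' @param targetFpr target false positive rate in [0, 1).
#' @return the threshold (flag when score > threshold).
#' @export
thresholdAtFpr <- function(scores, targetFpr) {
  n <- length(scores)
  stopifnot(targetFpr >= 0, targetFpr < 1)
  if (n < 100) stop("at least 100 null scores are required")
  if (targetFpr == 0) return(max(scores))
  if (targetFpr * n < 1)
    stop(sprintf(
      "target FPR %.4g is below the resolution of %d scores; need n >= %d",
      targetFpr, n, ceiling(1 / targetFpr)))
  sort(scores)[ceiling((1 - targetFpr) * n)]
}

#' Time to detect deterioration over growing subseries
#'
#' Runs the detector on the prefixes of length 3, 4, ..., Q; returns the
#' elapsed time from the first test to the last test of the first flagged
#' prefix, or the total span of the series when no prefix is flagged. A
#' detector failure on a prefix counts as not flagged.
#'
#' @param series a \linkS4class{VFSeries} with Q >= 3.
#' @param detector function mapping a \linkS4class{VFSeries} to TRUE/FALSE.
#' @return detection time in years.
#' @export
timeToDetect <- function(series, detector) {
  q <- length(series@times)
  stopifnot(q >= 3)
  for (k in 3:q) {
    prefix <- vfSeries(series@times[seq_len(k)],
                       series@values[seq_len(k), , drop = FALSE],
                       series@grid, series@eyeId)
    flagged <- tryCatch(isTRUE(detector(prefix)), error = function(e) {
      message("detector failed on a prefix of ", series@eyeId, ": ",
              conditionMessage(e))
      FALSE
    })
    if (flagged) return(series@times[k] - series@times[1])
  }
  series@times[q] - series@times[1]
}

#' Hit rate of a set of decisions
#' @param decisions logical deterioration calls over a cohort.
#' @return proportion flagged.
#' @export
hitRate <- function(decisions) mean(decisions)

#' Normalised partial area under a hit-rate curve
#'
#' Trapezoidal area of hit rate versus false positive rate over
#' [0, fprMax], divided by fprMax so a perfect curve scores 1.
#'
#' @param fpr false positive rates (must cover [0, fprMax]).
#' @param hit hit rates at those rates.
#' @param fprMax upper limit (0.15).
#' @return normalised partial AUC in [0, 1].
#' @export
partialAuc <- function(fpr, hit, fprMax = 0.15) {
  o <- order(fpr)
  fpr <- fpr[o]; hit <- hit[o]
  if (min(fpr) > 1e-12 || max(fpr) < fprMax - 1e-12)
    stop(sprintf("the FPR grid must cover [0, %g]", fprMax))
  if (max(fpr) > fprMax) {
    hEnd <- stats::approx(fpr, hit, xout = fprMax)$y
    keep <- fpr < fprMax
    fpr <- c(fpr[keep], fprMax); hit <- c(hit[keep], hEnd)
  }
  .trapz(fpr, hit) / fprMax
}

#' Score-based deterioration detectors
#'
#' `sdScorer` wraps [analyzeSeries()] into a scoring function returning the
#' deterioration index; `mdScorer` wraps [mdRegression()] into a monotone
#' score (1 - p for negative slopes, else 0).
#'
#' @param retest a \linkS4class{RetestModel}.
#' @param prior a \linkS4class{SpatialPrior}.
#' @param mode "ANSWERS" or "ANSWER".
#' @return a function mapping a \linkS4class{VFSeries} to a numeric score.
#' @export
sdScorer <- function(retest, prior, mode = "ANSWERS") {
  force(retest); force(prior); force(mode)
  function(series) deteriorationIndex(analyzeSeries(series, retest, prior,
                                                    mode = mode))
}

#' @rdname sdScorer
#' @param normative per-location expected sensitivities for the
#'   mean-deviation summary.
#' @export
mdScorer <- function(normative) {
  force(normative)
  function(series) mdRegression(series, normative)$score
}

#' Hit-rate curve of a score-based detector at calibrated thresholds
#'
#' For each target false positive rate, computes the threshold from the
#' null scores, the achieved null FPR and the cohort hit rate; also returns
#' the normalised partial AUC of the hit-rate curve over [0, 0.15].
#'
#' @param nullScores scores on stable (pseudo-) series.
#' @param cohortScores scores on the evaluation cohort.
#' @param fprGrid target false positive rates (covering [0, 0.15]).
#' @return list of class `EvaluationReport` with `curve` (data.frame:
#'   target_fpr, threshold, achieved_fpr, hit_rate) and `partialAuc`.
#' @export
evaluationReport <- function(nullScores, cohortScores,
                             fprGrid = seq(0, 0.15, by = 0.005)) {
  curve <- do.call(rbind, lapply(fprGrid, function(f) {
    thr <- thresholdAtFpr(nullScores, f)
    data.frame(target_fpr = f, threshold = thr,
               achieved_fpr = mean(nullScores > thr),
               hit_rate = mean(cohortScores > thr))
  }))
  structure(list(curve = curve,
                 partialAuc = partialAuc(curve$target_fpr, curve$hit_rate)),
            class = "EvaluationReport")
}

#' Compare detection methods at matched empirical false positive rates
#'
#' Implements the study's comparison protocol on synthetic data: every
#' score-based method (the spatial model, its no-spatial variant, and
#' mean-deviation regression) is calibrated on the same stable null series
#' to a common target false positive rate, and additionally to the achieved
#' false positive rate of point-wise linear regression with the given
#' contiguity criterion (whose discrete decision rule cannot be tuned
#' continuously). Hit rates are then compared on the evaluation cohort.
#'
#' @param retest a \linkS4class{RetestModel}.
#' @param prior a \linkS4class{SpatialPrior} (spatial; the no-spatial
#'   variant is derived internally).
#' @param nullSeries list of stable \linkS4class{VFSeries} (the null
#'   calibration set, same length as the cohort series).
#' @param cohortSeries list of \linkS4class{VFSeries} to evaluate.
#' @param normative per-location expected sensitivities for the
#'   mean-deviation summary.
#' @param targetFpr common false positive rate (default 5%).
#' @param contiguityN contiguity criterion for point-wise regression.
#' @return list of class `MethodComparison`: `nullScores`, `cohortScores`
#'   (per method), `thresholds`, `hitRates` and `achievedFpr` at the target
#'   rate, `plr` (achieved null FPR and cohort hit rate), and `hitRatesAtPlrFpr`
#'   (score methods re-thresholded at the PLR false positive rate).
#' @export
compareMethods <- function(retest, prior, nullSeries, cohortSeries,
                           normative, targetFpr = 0.05, contiguityN = 2) {
  scorers <- list(
    answers = sdScorer(retest, prior, "ANSWERS"),
    answer = sdScorer(retest, prior, "ANSWER"),
    md = mdScorer(normative))
  nullScores <- lapply(scorers, function(sc)
    vapply(nullSeries, sc, numeric(1)))
  cohortScores <- lapply(scorers, function(sc)
    vapply(cohortSeries, sc, numeric(1)))
  plrNull <- vapply(nullSeries, function(s)
    plr(s)$decision[[paste0("n", contiguityN)]], logical(1))
  plrCohort <- vapply(cohortSeries, function(s)
    plr(s)$decision[[paste0("n", contiguityN)]], logical(1))
  plrFpr <- mean(plrNull)

  thresholds <- lapply(nullScores, thresholdAtFpr, targetFpr = targetFpr)
  hitRates <- mapply(function(sc, thr) mean(sc > thr),
                     cohortScores, thresholds)
  achievedFpr <- mapply(function(ns, thr) mean(ns > thr),
                        nullScores, thresholds)
  matchFpr <- max(plrFpr, 1 / length(nullSeries))
  hitAtPlr <- mapply(function(ns, cs)
    mean(cs > thresholdAtFpr(ns, matchFpr)),
    nullScores, cohortScores)
  structure(list(
    nullScores = nullScores, cohortScores = cohortScores,
    thresholds = thresholds, hitRates = hitRates,
    achievedFpr = achievedFpr, targetFpr = targetFpr,
    plr = list(contiguityN = contiguityN, fpr = plrFpr,
               hitRate = mean(plrCohort)),
    hitRatesAtPlrFpr = hitAtPlr), class = "MethodComparison")
}

#' Time-to-detect comparison at a matched false positive rate
#'
#' For each series length L from 3 to the cohort's full length, thresholds
#' for the deterioration-index detector and the mean-deviation detector are
#' calibrated on the null series truncated to their first L tests; each
#' cohort series is then monitored prospectively ([timeToDetect()]) with
#' the per-length thresholds.
#'
#' @inheritParams compareMethods
#' @return list with per-series detection times (`answers`, `md`), their
#'   means, and the per-length `thresholds`.
#' @export
ttdComparison <- function(retest, prior, nullSeries, cohortSeries,
                          normative, targetFpr = 0.05) {
  q <- length(testTimes(cohortSeries[[1]]))
  scA <- sdScorer(retest, prior, "ANSWERS")
  scM <- mdScorer(normative)
  truncate <- function(s, L)
    vfSeries(testTimes(s)[seq_len(L)],
             sensitivities(s)[seq_len(L), , drop = FALSE], s@grid, s@eyeId)
  thrA <- thrM <- rep(NA_real_, q)
  for (L in 3:q) {
    nsA <- vapply(nullSeries, function(s) scA(truncate(s, L)), numeric(1))
    nsM <- vapply(nullSeries, function(s) scM(truncate(s, L)), numeric(1))
    thrA[L] <- thresholdAtFpr(nsA, targetFpr)
    thrM[L] <- thresholdAtFpr(nsM, targetFpr)
  }
  detA <- function(s) scA(s) > thrA[length(testTimes(s))]
  detM <- function(s) scM(s) > thrM[length(testTimes(s))]
  ttdA <- vapply(cohortSeries, timeToDetect, numeric(1), detector = detA)
  ttdM <- vapply(cohortSeries, timeToDetect, numeric(1), detector = detM)
  list(answers = ttdA, md = ttdM,
       meanAnswers = mean(ttdA), meanMd = mean(ttdM),
       thresholds = list(answers = thrA, md = thrM))
}
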