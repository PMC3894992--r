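# Comparator methods: ordinary linear regression of a mean-deviation-style
# summary, and point-wise linear regression with contiguity criteria.

#' Ordinary least squares fit with a slope t-test
#'
#' Least-squares line through (times, values) with the standard two-sided
#' t-test on the slope (Q - 2 degrees of freedom). A series with zero
#' residual and zero slope variance (constant values) returns slope 0 with
#' p = 1.
#'
#' @param times at least 3 time points, not all equal.
#' @param values response values.
#' @return list with `slope`, `intercept`, `p`.
#' @export
olsFit <- function(times, values) {
  stopifnot(length(times) >= 3, length(values) == length(times))
  if (stats::sd(times) == 0) stop("degenerate design: times all equal")
  if (stats::sd(values) == 0)
    return(list(slope = 0, intercept = values[1], p = 1))
  fit <- stats::lm(values ~ times)
  sm <- suppressWarnings(stats::summary.lm(fit))$coefficients
  p <- sm["times", "Pr(>|t|)"]
  if (is.nan(p)) p <- 1                   # exact fit: zero residual variance
  list(slope = unname(sm["times", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       p = unname(p))
}

# Vectorised per-location OLS over the columns of a Q x M matrix.
.olsMatrix <- function(times, values) {
  q <- length(times)
  co <- matrix(stats::coef(stats::lm(values ~ times)), nrow = 2)
  res <- values - cbind(1, times) %*% co
  sxx <- sum((times - mean(times))^2)
  s2 <- colSums(res^2) / (q - 2)
  se <- sqrt(s2 / sxx)
  tstat <- ifelse(se > 1e-12, co[2, ] / se, 0)
  p <- ifelse(se > 1e-12, 2 * stats::pt(-abs(tstat), df = q - 2), 1)
  # a perfectly fitted non-zero slope is maximally significant; an exactly
  # constant column (slope 0 to rounding) is maximally insignificant
  p[se <= 1e-12 & abs(co[2, ]) > 1e-8] <- 0
  list(slopes = unname(co[2, ]), intercepts = unname(co[1, ]), p = unname(p))
}

#' Mean-deviation regression
#'
#' Summarises each test as the unweighted mean deviation of the measured
#' sensitivities from a supplied normative (healthy-expectation) vector,
#' then fits an ordinary least-squares line over time. The series is
#' deteriorating when the slope is negative with p below the threshold.
#'
#' @param series a \linkS4class{VFSeries}.
#' @param normative per-location expected sensitivities (dB).
#' @param pThreshold significance threshold for the deterioration call.
#' @return list of class `MDResult` with `mdSeries`, `slope`, `p`,
#'   `deteriorating` and `score` (1 - p for negative slopes, 0 otherwise; a
#'   monotone score usable for false-positive-rate calibration).
#' @export
mdRegression <- function(series, normative, pThreshold = 0.05) {
  if (missing(normative) || is.null(normative))
    stop("a normative per-location sensitivity vector is required")
  stopifnot(length(normative) == nLocations(series))
  md <- rowMeans(sweep(series@values, 2, normative))
  fit <- olsFit(series@times, md)
  structure(list(mdSeries = md, slope = fit$slope, p = fit$p,
                 deteriorating = fit$slope < 0 & fit$p < pThreshold,
                 score = if (fit$slope < 0) 1 - fit$p else 0),
            class = "MDResult")
}

# Connected components of `flagged` locations under an adjacency matrix.
.flaggedClusters <- function(flagged, adj) {
  idx <- which(flagged)
  comps <- list()
  seen <- logical(length(flagged))
  for (v in idx) {
    if (seen[v]) next
    comp <- v; queue <- v; seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[u, ] & flagged & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Point-wise linear regression with contiguity criteria
#'
#' Fits an ordinary least-squares line per location; a location is
#' deteriorating when its slope is negative with p < `pThreshold` (1% by
#' default). Deteriorating locations are grouped into maximal connected
#' clusters under the grid's 4-neighbour adjacency, by default restricted to
#' within-hemifield edges (nerve-fibre anatomy does not cross the horizontal
#' midline); the series is flagged at contiguity criterion n when some
#' cluster has at least n locations.
#'
#' @param series a \linkS4class{VFSeries}.
#' @param pThreshold per-location significance threshold.
#' @param contiguity adjacency rule: "within-hemifield-4" (default) or "4"
#'   (allows clusters across the midline).
#' @return list of class `PLRResult` with `slopes`, `p`, `deteriorating`
#'   (per location), `clusters`, and `decision` (logical for n = 1..4).
#' @export
plr <- function(series, pThreshold = 0.01,
                contiguity = c("within-hemifield-4", "4")) {
  contiguity <- match.arg(contiguity)
  stopifnot(length(series@times) >= 3)
  fit <- .olsMatrix(series@times, series@values)
  det <- fit$slopes < 0 & fit$p < pThreshold
  adj <- adjacency(series@grid)
  if (contiguity == "within-hemifield-4") {
    hemi <- locations(series@grid)$hemifield
    adj <- adj & outer(hemi, hemi, "==")
  }
  clusters <- .flaggedClusters(det, adj)
  sizes <- vapply(clusters, length, integer(1))
  maxSize <- if (length(sizes)) max(sizes) else 0L
  structure(list(slopes = fit$slopes, p = fit$p, deteriorating = det,
                 clusters = clusters,
                 decision = stats::setNames(maxSize >= 1:4,
                                            paste0("n", 1:4))),
            class = "PLRResult")
}
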