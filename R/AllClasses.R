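#' @import methods
NULL

#' VisualFieldGrid: geometry of the analysed perimetry test pattern
#'
#' Holds the analysed test locations of a visual-field test pattern (24-2 by
#' default, 52 locations after blind-spot exclusion), their coordinates in
#' degrees of visual angle, hemifield labels, nerve-fibre entry angles at the
#' optic nerve head, and the 4-neighbour adjacency relation at the 6-degree
#' grid spacing.
#'
#' @slot locations data.frame with columns `index` (0-based), `x_deg`,
#'   `y_deg`, `hemifield` ("superior"/"inferior"), `fibre_angle_deg`.
#' @slot adjacency logical M x M symmetric, irreflexive 4-neighbour relation.
#' @slot eye "right" or "left".
#' @export
setClass("VisualFieldGrid",
  representation(locations = "data.frame", adjacency = "matrix",
                 eye = "character"),
  validity = function(object) {
    loc <- object@locations
    msg <- character()
    need <- c("index", "x_deg", "y_deg", "hemifield", "fibre_angle_deg")
    if (!all(need %in% names(loc)))
      msg <- c(msg, paste("locations must have columns",
                          paste(need, collapse = ", ")))
    m <- nrow(loc)
    if (m < 1L) msg <- c(msg, "grid must have at least one location")
    adj <- object@adjacency
    if (!is.logical(adj) || nrow(adj) != m || ncol(adj) != m)
      msg <- c(msg, "adjacency must be a logical M x M matrix")
    else {
      if (!isTRUE(all(adj == t(adj)))) msg <- c(msg, "adjacency not symmetric")
      if (any(diag(adj))) msg <- c(msg, "adjacency must be irreflexive")
    }
    if (length(msg) == 0 &&
        !all(loc$hemifield[loc$y_deg > 0] == "superior",
             loc$hemifield[loc$y_deg < 0] == "inferior"))
      msg <- c(msg, "hemifield labels must match the sign of y_deg")
    if (length(msg)) msg else TRUE
  })

#' SpatialPrior: multivariate normal prior over slopes and intercepts
#'
#' The unscaled correlation matrix `psi` couples same-hemifield locations
#' through a kernel in Euclidean distance and nerve-fibre entry-angle
#' difference; `a * psi` and `b * psi` are the prior covariances of the slope
#' and intercept vectors respectively.
#'
#' @slot psi M x M unscaled correlation matrix (unit diagonal, entries in
#'   [0,1], zero across the horizontal midline).
#' @slot a slope covariance scale ((dB/year)^2).
#' @slot b intercept covariance scale (dB^2).
#' @slot muSlope,muIntercept prior means (dB/year, dB).
#' @slot sigmaD,sigmaTheta kernel scales (degrees).
#' @slot kernel kernel name used to build `psi`.
#' @export
setClass("SpatialPrior",
  representation(psi = "matrix", a = "numeric", b = "numeric",
                 muSlope = "numeric", muIntercept = "numeric",
                 sigmaD = "numeric", sigmaTheta = "numeric",
                 kernel = "character"),
  validity = function(object) {
    p <- object@psi
    msg <- character()
    if (nrow(p) != ncol(p)) msg <- c(msg, "psi must be square")
    else {
      if (max(abs(p - t(p))) > 1e-12) msg <- c(msg, "psi not symmetric")
      if (max(abs(diag(p) - 1)) > 1e-12) msg <- c(msg, "psi diagonal must be 1")
      if (any(p < -1e-12 | p > 1 + 1e-12)) msg <- c(msg, "psi entries must lie in [0,1]")
    }
    if (object@a <= 0 || object@b <= 0) msg <- c(msg, "scales a, b must be positive")
    if (length(msg)) msg else TRUE
  })

#' RetestModel: per-level Weibull mixture retest distributions
#'
#' One K-component Weibull mixture per integer sensitivity level, with smooth
#' (cubic, log/logit-space) interpolation of the mixture parameters across
#' levels so the log density is continuously differentiable in the predicted
#' level.
#'
#' @slot levels integer levels covered (0:35 dB).
#' @slot weights,alphas,betas L x K matrices of mixture parameters.
#' @slot K component count.
#' @slot selectedK component count chosen by cross-validation (NA if fixed).
#' @slot transformKnot knot of the low-end sensitivity transform (dB).
#' @export
setClass("RetestModel",
  representation(levels = "integer", weights = "matrix", alphas = "matrix",
                 betas = "matrix", K = "integer", selectedK = "integer",
                 transformKnot = "numeric"),
  validity = function(object) {
    L <- length(object@levels)
    K <- object@K
    msg <- character()
    for (nm in c("weights", "alphas", "betas")) {
      m <- slot(object, nm)
      if (nrow(m) != L || ncol(m) != K)
        msg <- c(msg, sprintf("%s must be %d x %d", nm, L, K))
    }
    if (length(msg) == 0) {
      if (any(object@alphas <= 0) || any(object@betas <= 0))
        msg <- c(msg, "alphas and betas must be positive")
      if (any(object@weights < 0) ||
          max(abs(rowSums(object@weights) - 1)) > 1e-8)
        msg <- c(msg, "weights must be non-negative and sum to 1 per level")
    }
    if (length(msg)) msg else TRUE
  })

#' VFSeries: a visual-field time series for one eye
#'
#' @slot times test times in years from the first retained test, strictly
#'   increasing.
#' @slot values Q x M matrix of differential light sensitivities (dB).
#' @slot grid the \linkS4class{VisualFieldGrid} the columns refer to.
#' @slot eyeId identifier.
#' @export
setClass("VFSeries",
  representation(times = "numeric", values = "matrix",
                 grid = "VisualFieldGrid", eyeId = "character"),
  validity = function(object) {
    msg <- character()
    q <- length(object@times)
    if (nrow(object@values) != q)
      msg <- c(msg, "values must have one row per test time")
    if (q > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (ncol(object@values) != nrow(object@grid@locations))
      msg <- c(msg, "values must have one column per grid location")
    if (q > 0 && (any(!is.finite(object@values)) ||
        any(object@values < 0) || any(object@values > 50)))
      msg <- c(msg, "sensitivities must be finite and within [0, 50] dB")
    if (length(msg)) msg else TRUE
  })

#' PosteriorEstimate: MAP trend estimate with Laplace uncertainty
#'
#' @slot slopes,intercepts MAP per-location trend (dB/year, dB).
#' @slot covariance 2M x 2M Laplace covariance, slopes first.
#' @slot pnd per-location probability of no deterioration, P(slope >= 0).
#' @slot sD,sI global deterioration / improvement indices.
#' @slot logPosterior log posterior (up to a constant) at the mode.
#' @slot converged logical convergence flag from the optimiser.
#' @slot mode "ANSWERS" (spatial prior) or "ANSWER" (diagonal prior).
#' @slot eyeId identifier carried from the series.
#' @export
setClass("PosteriorEstimate",
  representation(slopes = "numeric", intercepts = "numeric",
                 covariance = "matrix", pnd = "numeric",
                 sD = "numeric", sI = "numeric", logPosterior = "numeric",
                 converged = "logical", mode = "character",
                 eyeId = "character"),
  validity = function(object) {
    m <- length(object@slopes)
    msg <- character()
    if (length(object@intercepts) != m)
      msg <- c(msg, "slopes and intercepts must have equal length")
    if (nrow(object@covariance) != 2 * m || ncol(object@covariance) != 2 * m)
      msg <- c(msg, "covariance must be 2M x 2M")
    if (length(object@pnd) != m || any(object@pnd < 0 | object@pnd > 1))
      msg <- c(msg, "pnd must be M probabilities in [0,1]")
    if (object@sD < 0 || object@sI < 0)
      msg <- c(msg, "indices must be non-negative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "VisualFieldGrid", function(object) {
  cat(sprintf("VisualFieldGrid (%s eye): %d locations, %d adjacency edges\n",
              object@eye, nrow(object@locations),
              sum(object@adjacency) / 2L))
})

setMethod("show", "SpatialPrior", function(object) {
  off <- object@psi[upper.tri(object@psi)]
  cat(sprintf(paste0(
    "SpatialPrior: M = %d, kernel = %s (sigma_d = %g deg, sigma_theta = %g deg)\n",
    "  slope ~ MVN(%g, %g * Psi), intercept ~ MVN(%g, %g * Psi)\n",
    "  off-diagonal Psi: %d non-zero of %d\n"),
    nrow(object@psi), object@kernel, object@sigmaD, object@sigmaTheta,
    object@muSlope, object@a, object@muIntercept, object@b,
    sum(off > 0), length(off)))
})

setMethod("show", "RetestModel", function(object) {
  cat(sprintf(
    "RetestModel: %d-component Weibull mixtures at levels %d..%d dB%s\n",
    object@K, min(object@levels), max(object@levels),
    if (is.na(object@selectedK)) "" else
      sprintf(" (K selected by cross-validation: %d)", object@selectedK)))
})

setMethod("show", "VFSeries", function(object) {
  cat(sprintf("VFSeries '%s': %d tests over %.2f years, %d locations\n",
              object@eyeId, length(object@times),
              if (length(object@times)) diff(range(object@times)) else 0,
              ncol(object@values)))
})

setMethod("show", "PosteriorEstimate", function(object) {
  cat(sprintf(paste0(
    "PosteriorEstimate (%s%s): %d locations\n",
    "  mean slope %.3f dB/year (range %.3f to %.3f)\n",
    "  S_d = %.3f, S_i = %.3f\n"),
    object@mode, if (object@converged) "" else ", NOT converged",
    length(object@slopes), mean(object@slopes), min(object@slopes),
    max(object@slopes), object@sD, object@sI))
})

# ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @param object an object from this package.
#' @export
setGeneric("nLocations", function(object) standardGeneric("nLocations"))
#' Accessors for the package's core classes
#' @name accessors
#' @rdname accessors
#' @export
setMethod("nLocations", "VisualFieldGrid",
          function(object) nrow(object@locations))
#' @rdname accessors
#' @export
setMethod("nLocations", "VFSeries", function(object) ncol(object@values))

#' @rdname accessors
#' @export
setGeneric("locations", function(object) standardGeneric("locations"))
#' @rdname accessors
#' @export
setMethod("locations", "VisualFieldGrid", function(object) object@locations)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "VisualFieldGrid", function(object) object@adjacency)

#' @rdname accessors
#' @export
setGeneric("psi", function(object) standardGeneric("psi"))
#' @rdname accessors
#' @export
setMethod("psi", "SpatialPrior", function(object) object@psi)

#' @rdname accessors
#' @export
setGeneric("testTimes", function(object) standardGeneric("testTimes"))
#' @rdname accessors
#' @export
setMethod("testTimes", "VFSeries", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("sensitivities", function(object) standardGeneric("sensitivities"))
#' @rdname accessors
#' @export
setMethod("sensitivities", "VFSeries", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("slopes", function(object) standardGeneric("slopes"))
#' @rdname accessors
#' @export
setMethod("slopes", "PosteriorEstimate", function(object) object@slopes)

#' @rdname accessors
#' @export
setGeneric("intercepts", function(object) standardGeneric("intercepts"))
#' @rdname accessors
#' @export
setMethod("intercepts", "PosteriorEstimate", function(object) object@intercepts)

#' @rdname accessors
#' @export
setGeneric("slopeSD", function(object) standardGeneric("slopeSD"))
#' @rdname accessors
#' @export
setMethod("slopeSD", "PosteriorEstimate", function(object) {
  m <- length(object@slopes)
  sqrt(diag(object@covariance)[seq_len(m)])
})

#' @rdname accessors
#' @export
setGeneric("pnd", function(object) standardGeneric("pnd"))
#' @rdname accessors
#' @export
setMethod("pnd", "PosteriorEstimate", function(object) object@pnd)

#' @rdname accessors
#' @export
setGeneric("deteriorationIndex",
           function(object) standardGeneric("deteriorationIndex"))
#' @rdname accessors
#' @export
setMethod("deteriorationIndex", "PosteriorEstimate",
          function(object) object@sD)

#' @rdname accessors
#' @export
setGeneric("improvementIndex",
           function(object) standardGeneric("improvementIndex"))
#' @rdname accessors
#' @export
setMethod("improvementIndex", "PosteriorEstimate", function(object) object@sI)
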