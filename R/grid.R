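# 24-2 test-pattern geometry and construction of VisualFieldGrid objects.

# Right-eye 24-2 coordinates (degrees of visual angle): 54 points in rows of
# 4/6/8/9/9/8/6/4, 6-degree spacing, nasal extension to -27 at y = +-3,
# blind spot at (15, +-3).
.pattern242 <- function() {
  rows <- list(
    c( 21, -9,  9), c( 15, -15, 15), c(  9, -21, 21), c(  3, -27, 21),
    c( -3, -27, 21), c( -9, -21, 21), c(-15, -15, 15), c(-21, -9,  9))
  out <- do.call(rbind, lapply(rows, function(r) {
    x <- seq(r[2], r[3], by = 6)
    data.frame(x_deg = x, y_deg = r[1])
  }))
  out
}

.blindSpot242 <- function() data.frame(x_deg = c(15, 15), y_deg = c(3, -3))

# Model-derived per-location nerve-fibre entry angle (degrees) for a RIGHT
# eye: angle of the straight segment from the optic nerve head (15, 2 deg,
# hemifield-reflected) to the location, forced into the hemifield's half
# circle. A synthetic stand-in for the published anatomical map; the packaged
# CSV (inst/extdata) is generated from this model and can be overridden.
.fibreAngleModel <- function(x, y) {
  s <- ifelse(y > 0, 1, -1)
  ang <- atan2(y - 2 * s, x - 15) * 180 / pi
  # keep superior angles in (0, 180), inferior in (-180, 0)
  ang <- ifelse(s > 0, pmin(pmax(ang, 2), 178), pmin(pmax(ang, -178), -2))
  ang
}

.defaultFibreMapPath <- function() {
  system.file("extdata", "fibre_angle_map_24_2_synthetic.csv",
              package = "answers", mustWork = FALSE)
}

#' Build the analysed 24-2 visual-field grid
#'
#' Returns the 52 analysed locations of the 24-2 test pattern (the 54-point
#' pattern minus the two blind-spot locations), with coordinates in degrees,
#' hemifield labels, nerve-fibre entry angles and the 4-neighbour adjacency
#' at the 6-degree spacing. The left-eye grid is the mirror image of the
#' right-eye grid (x negated, fibre angles reflected about the vertical).
#'
#' @param eye "right" (canonical) or "left".
#' @param fibreAngleMap optional data.frame or CSV path with columns
#'   `x_deg`, `y_deg`, `fibre_angle_deg` giving right-eye entry angles; the
#'   packaged model-derived table is used by default.
#' @return a \linkS4class{VisualFieldGrid}.
#' @examples
#' g <- buildGrid("right")
#' nLocations(g)  # 52
#' @export
buildGrid <- function(eye = c("right", "left"), fibreAngleMap = NULL) {
  eye <- match.arg(eye)
  pts <- .pattern242()
  bs <- .blindSpot242()
  keep <- !(paste(pts$x_deg, pts$y_deg) %in% paste(bs$x_deg, bs$y_deg))
  pts <- pts[keep, , drop = FALSE]

  fam <- fibreAngleMap
  if (is.null(fam)) {
    path <- .defaultFibreMapPath()
    fam <- if (nzchar(path) && file.exists(path))
      utils::read.csv(path) else NULL
  } else if (is.character(fam)) {
    fam <- utils::read.csv(fam)
  }
  if (is.null(fam)) {
    ang <- .fibreAngleModel(pts$x_deg, pts$y_deg)
  } else {
    key <- paste(fam$x_deg, fam$y_deg)
    idx <- match(paste(pts$x_deg, pts$y_deg), key)
    if (anyNA(idx)) {
      miss <- pts[is.na(idx), c("x_deg", "y_deg")]
      stop("fibre-angle map is missing entries for location(s): ",
           paste(sprintf("(%g, %g)", miss$x_deg, miss$y_deg), collapse = ", "))
    }
    ang <- fam$fibre_angle_deg[idx]
  }

  if (eye == "left") {
    pts$x_deg <- -pts$x_deg
    ang <- ifelse(pts$y_deg > 0, 180 - ang, -180 - ang)
  }

  loc <- data.frame(
    index = seq_len(nrow(pts)) - 1L,
    x_deg = pts$x_deg, y_deg = pts$y_deg,
    hemifield = ifelse(pts$y_deg > 0, "superior", "inferior"),
    fibre_angle_deg = ang,
    stringsAsFactors = FALSE)
  rownames(loc) <- NULL

  d <- as.matrix(stats::dist(loc[, c("x_deg", "y_deg")]))
  adj <- abs(d - 6) < 1e-9
  diag(adj) <- FALSE
  new("VisualFieldGrid", locations = loc, adjacency = adj, eye = eye)
}

#' Pairwise Euclidean distances between grid locations (degrees)
#' @param grid a \linkS4class{VisualFieldGrid}.
#' @return M x M matrix.
#' @export
locationDistances <- function(grid) {
  as.matrix(stats::dist(locations(grid)[, c("x_deg", "y_deg")]))
}
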