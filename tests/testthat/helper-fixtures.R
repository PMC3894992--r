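# Shared fixtures: tiny grids, analytic retest models and cached synthetic
# data. Everything is built in code; the only file fixture is the packaged
# fitted retest model.

# A minimal grid with `m` locations on one horizontal line in the superior
# hemifield (same hemifield, chain adjacency).
toyGrid <- function(m = 2) {
  loc <- data.frame(
    index = seq_len(m) - 1L,
    x_deg = seq(-3, by = 6, length.out = m),
    y_deg = rep(3, m),
    hemifield = rep("superior", m),
    fibre_angle_deg = seq(120, by = -10, length.out = m),
    stringsAsFactors = FALSE)
  adj <- abs(outer(loc$x_deg, loc$x_deg, "-")) == 6
  diag(adj) <- FALSE
  new("VisualFieldGrid", locations = loc, adjacency = adj, eye = "right")
}

# Analytic retest model: a single Weibull component per level whose mean
# tracks the level with constant coefficient of variation -> smooth in mu by
# construction. K = 2 with equal duplicated components keeps the class
# general without changing the density.
toyRetestModel <- function(shape = 8) {
  lv <- 0:35
  mean <- pmax(lv, 0.8)
  beta <- mean / gamma(1 + 1 / shape)
  W <- matrix(0.5, length(lv), 2)
  A <- matrix(shape, length(lv), 2)
  B <- cbind(beta, beta)
  retestModel(W, A, B, levels = lv)
}

# The packaged fitted retest model (fitted once from the synthetic
# test-retest generator at its default study conditions).
packagedRetestModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- readRetestModel(system.file("extdata",
        "retest_model_synthetic.json", package = "answers"))
    cache
  }
})

fullGrid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildGrid()
    cache
  }
})

fullPrior <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildSpatialPrior(fullGrid())
    cache
  }
})

# Deterministic small VFSeries on the toy grid.
toySeries <- function(values, times = seq_len(nrow(values)) - 1,
                      grid = toyGrid(ncol(values))) {
  vfSeries(times, values, grid, eyeId = "toy")
}
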