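# Internal numerical helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.logSumExpRows <- function(m) {
  mx <- pmax(apply(m, 1L, max), -745)   # guard all--Inf rows
  mx + log(rowSums(exp(m - mx)))
}

#' Smoothly clamp predicted sensitivity into the modelled range
#'
#' Maps any real predicted level into the open interval (lo, hi) using
#' softplus corners, so the retest density lookup stays differentiable in the
#' predicted level. Away from the corners (more than ~1 dB at the default
#' sharpness) the map is the identity to machine precision.
#'
#' @param mu numeric vector of predicted levels (dB).
#' @param lo,hi range of the retest model (dB).
#' @param sharpness corner sharpness; larger is closer to a hard clamp.
#' @return list with `value` and `deriv`, both vectors like `mu`.
#' @export
smoothClamp <- function(mu, lo = 0, hi = 35, sharpness = 10) {
  s <- sharpness
  a <- s * (mu - lo)
  l <- lo + .softplus(a) / s
  dl <- stats::plogis(a)
  b <- s * (hi - l)
  v <- hi - .softplus(b) / s
  dv <- stats::plogis(b) * dl
  list(value = v, deriv = dv)
}

# Trapezoidal integral of y over x (x ascending).
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Short content hash of an R object (used to stamp outputs with the config).
.configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
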