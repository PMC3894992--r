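# Vectorised natural-cubic-spline machinery: every observation gets its own
# spline of log p(y_obs | mu) over a shared grid of predicted levels, built
# with a single tridiagonal solve, so the regression objective and its
# gradient evaluate in O(observations) vectorised work.

# Natural cubic splines for the rows of Y over knots x (shared by all rows).
# Returns an object for .rowSplineEval.
.rowSplineCoefs <- function(x, Y) {
  n <- length(x)
  stopifnot(ncol(Y) == n, n >= 3)
  h <- diff(x)
  # tridiagonal system for interior second derivatives (natural: m1 = mn = 0)
  ni <- n - 2
  T <- matrix(0, ni, ni)
  for (i in seq_len(ni)) {
    T[i, i] <- (h[i] + h[i + 1]) / 3
    if (i > 1) T[i, i - 1] <- h[i] / 6
    if (i < ni) T[i, i + 1] <- h[i + 1] / 6
  }
  D <- (Y[, -(1:2), drop = FALSE] - Y[, -c(1, n), drop = FALSE]) /
    rep(h[-1], each = nrow(Y))
  D0 <- (Y[, -c(1, n), drop = FALSE] - Y[, -((n - 1):n), drop = FALSE]) /
    rep(h[-(n - 1)], each = nrow(Y))
  R <- t(D - D0)                                  # ni x nRows
  Mint <- solve(T, R)                             # interior second derivs
  M <- rbind(0, Mint, 0)                          # n x nRows
  list(x = x, Y = Y, M = t(M), h = h)
}

# Evaluate row i of the spline set at mu[i]; returns value and derivative.
.rowSplineEval <- function(sp, mu) {
  x <- sp$x; h <- sp$h
  i <- findInterval(mu, x, all.inside = TRUE)
  rows <- seq_along(mu)
  hi <- h[i]
  xl <- x[i]; xr <- x[i + 1]
  yl <- sp$Y[cbind(rows, i)]; yr <- sp$Y[cbind(rows, i + 1)]
  ml <- sp$M[cbind(rows, i)]; mr <- sp$M[cbind(rows, i + 1)]
  a <- (xr - mu); b <- (mu - xl)
  f <- ml * a^3 / (6 * hi) + mr * b^3 / (6 * hi) +
    (yl / hi - ml * hi / 6) * a + (yr / hi - mr * hi / 6) * b
  df <- -ml * a^2 / (2 * hi) + mr * b^2 / (2 * hi) -
    (yl / hi - ml * hi / 6) + (yr / hi - mr * hi / 6)
  list(value = f, deriv = df)
}
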