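# Brute-force oracles, independent of the package's interpolation and
# colorimetry code paths.

# polynomial interpolation through all given nodes via a Vandermonde solve
oracle_poly_interp <- function(x, y, q) {
  n <- length(x)
  v <- outer(x, 0:(n - 1), "^")
  coef <- solve(v, y)
  vq <- outer(q, 0:(n - 1), "^")
  as.numeric(vq %*% coef)
}

# piecewise 4-point cubic with the same stencil rule as the package:
# nearest two nodes per side, one-sided near the ends, mirror-reflected
# queries
oracle_piecewise_cubic <- function(x, y, q) {
  n <- length(x)
  span <- x[n] - x[1]
  qr <- vapply(q, function(qi) {
    t <- (qi - x[1]) %% (2 * span)
    if (t > span) t <- 2 * span - t
    x[1] + t
  }, numeric(1))
  vapply(qr, function(qi) {
    if (n < 4) return(oracle_poly_interp(x, y, qi))
    i <- findInterval(qi, x, all.inside = TRUE)
    s <- min(max(i - 1, 1), n - 3)
    nodes <- s:(s + 3)
    oracle_poly_interp(x[nodes], y[nodes], qi)
  }, numeric(1))
}

# natural cubic spline by explicit tridiagonal system for the second
# derivatives
oracle_natural_spline <- function(x, y, q) {
  n <- length(x)
  stopifnot(n >= 3)
  h <- diff(x)
  a <- matrix(0, n, n)
  b <- numeric(n)
  a[1, 1] <- 1; a[n, n] <- 1
  for (i in 2:(n - 1)) {
    a[i, i - 1] <- h[i - 1] / 6
    a[i, i] <- (h[i - 1] + h[i]) / 3
    a[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  m <- solve(a, b)
  span <- x[n] - x[1]
  vapply(q, function(qi) {
    t <- (qi - x[1]) %% (2 * span)
    if (t > span) t <- 2 * span - t
    qi <- x[1] + t
    i <- findInterval(qi, x, all.inside = TRUE)
    hh <- x[i + 1] - x[i]
    aa <- (x[i + 1] - qi) / hh
    bb <- (qi - x[i]) / hh
    aa * y[i] + bb * y[i + 1] +
      ((aa^3 - aa) * m[i] + (bb^3 - bb) * m[i + 1]) * hh^2 / 6
  }, numeric(1))
}

# bicubic interpolation on a 4x4 node grid via a 16-coefficient tensor
# Vandermonde solve
oracle_bicubic <- function(xr, xc, z, qr, qc) {
  stopifnot(length(xr) == 4, length(xc) == 4, all(dim(z) == c(4, 4)))
  # center the coordinates (interpolation is affine-invariant) so the
  # monomial basis stays well-conditioned
  qr <- qr - mean(xr); xr <- xr - mean(xr)
  qc <- qc - mean(xc); xc <- xc - mean(xc)
  a <- matrix(0, 16, 16)
  b <- numeric(16)
  k <- 1
  for (i in 1:4) for (j in 1:4) {
    a[k, ] <- as.vector(outer(xr[i]^(0:3), xc[j]^(0:3)))
    b[k] <- z[i, j]
    k <- k + 1
  }
  coef <- solve(a, b)
  sum(coef * as.vector(outer(qr^(0:3), qc^(0:3))))
}

# textbook linear-RGB (sRGB primaries, D65) -> CIELAB, written independently
# of the package implementation (scalar, loop-based)
oracle_lab <- function(rgb) {
  m <- matrix(c(0.41239080, 0.35758434, 0.18048079,
                0.21263901, 0.71516868, 0.07219232,
                0.01933082, 0.11919478, 0.95053215),
              3, 3, byrow = TRUE)
  xyz <- as.numeric(m %*% rgb)
  wp <- as.numeric(m %*% c(1, 1, 1))
  fvals <- numeric(3)
  for (i in 1:3) {
    t <- xyz[i] / wp[i]
    fvals[i] <- if (t > (6 / 29)^3) t^(1 / 3)
    else t / (3 * (6 / 29)^2) + 4 / 29
  }
  c(116 * fvals[2] - 16,
    500 * (fvals[1] - fvals[2]),
    200 * (fvals[2] - fvals[3]))
}

# small scene used across tests
small_params <- function(seed = 1, h = 48, w = 48) {
  synth_params(seed = seed, height = h, width = w,
               background_smoothness = 6, n_vessels = 2, n_blobs = 2,
               blob_sigma_range = c(2, 4))
}

pooled_mae <- function(truth, est, fg, known) {
  mae <- vapply(scene_channels(), function(ch) {
    if (all(is.na(est[, , ch]))) NA_real_
    else mean_absolute_error(truth, est, fg, known, ch)
  }, numeric(1))
  c(vis = mean(mae[1:3], na.rm = TRUE), nir = mean(mae[4:6], na.rm = TRUE))
}
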