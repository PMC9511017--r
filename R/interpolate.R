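# Interpolation kernels shared by the demosaicing routines: piecewise-linear,
# piecewise 4-point Lagrange cubics, and natural cubic splines, in one
# dimension and as tensor products on rectangular (or 45-degree-rotated
# quincunx) lattices.  All kernels are interpolants — exact at the known
# samples — and handle queries beyond the known span by mirror reflection
# about the end samples.

.lagrange_eval <- function(xs, ys, q) {
  out <- numeric(length(q))
  for (j in seq_along(xs)) {
    lj <- rep(1, length(q))
    for (m in seq_along(xs))
      if (m != j) lj <- lj * (q - xs[m]) / (xs[j] - xs[m])
    out <- out + ys[j] * lj
  }
  out
}

#' Interpolate along one line of samples
#'
#' The 1-D kernel underlying all demosaicing routines.
#'
#' * `"linear"`: piecewise-linear between the bracketing samples.
#' * `"cubic_poly"`: piecewise cubic Lagrange polynomial through the 4
#'   nearest known samples (two per side; one-sided near the ends of the
#'   line).  With fewer than 4 samples the degree drops to
#'   `length(known_positions) - 1`.
#' * `"cubic_spline"`: natural cubic spline (zero second derivative at the
#'   end knots) through all known samples of the line; with 2 samples this
#'   degenerates to linear interpolation.
#'
#' Queries outside the known span are mirror-reflected into it; all kernels
#' are exact at the known positions.
#'
#' @param known_positions Strictly increasing numeric positions (>= 1
#'   sample).
#' @param known_values Sample values, same length.
#' @param query_positions Positions at which to evaluate.
#' @param kind `"linear"`, `"cubic_poly"`, or `"cubic_spline"`.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_line <- function(known_positions, known_values, query_positions,
                             kind = c("linear", "cubic_poly",
                                      "cubic_spline")) {
  kind <- match.arg(kind)
  n <- length(known_positions)
  if (n == 0L)
    .stopf("coverage_error", "no known samples to interpolate from")
  if (length(known_values) != n)
    .stopf("param_error", "positions and values differ in length")
  if (n > 1L && any(diff(known_positions) <= 0))
    .stopf("param_error", "'known_positions' must be strictly increasing")
  if (any(!is.finite(known_positions)) || any(!is.finite(known_values)))
    .stopf("param_error", "samples must be finite")
  if (n == 1L) return(rep(known_values, length(query_positions)))
  q <- .reflect_into(query_positions, known_positions[1], known_positions[n])
  switch(kind,
    linear = stats::approx(known_positions, known_values, xout = q)$y,
    cubic_spline = {
      if (n == 2L) stats::approx(known_positions, known_values, xout = q)$y
      else stats::spline(known_positions, known_values, xout = q,
                         method = "natural")$y
    },
    cubic_poly = {
      if (n < 4L) return(.lagrange_eval(known_positions, known_values, q))
      i <- findInterval(q, known_positions, all.inside = TRUE)
      s <- pmin(pmax(i - 1L, 1L), n - 3L)
      x0 <- known_positions[s];      y0 <- known_values[s]
      x1 <- known_positions[s + 1L]; y1 <- known_values[s + 1L]
      x2 <- known_positions[s + 2L]; y2 <- known_values[s + 2L]
      x3 <- known_positions[s + 3L]; y3 <- known_values[s + 3L]
      y0 * (q - x1) * (q - x2) * (q - x3) /
        ((x0 - x1) * (x0 - x2) * (x0 - x3)) +
        y1 * (q - x0) * (q - x2) * (q - x3) /
          ((x1 - x0) * (x1 - x2) * (x1 - x3)) +
        y2 * (q - x0) * (q - x1) * (q - x3) /
          ((x2 - x0) * (x2 - x1) * (x2 - x3)) +
        y3 * (q - x0) * (q - x1) * (q - x2) /
          ((x3 - x0) * (x3 - x1) * (x3 - x2))
    })
}

#' Tensor-product interpolation on a sampling lattice
#'
#' Evaluates a separable (tensor-product) cubic interpolant from values given
#' on a rectangular grid of knots.  For `lattice = "rectangular"` the knot
#' grid and the query sites live in the same (row, col) coordinates.  For
#' `lattice = "quincunx"` the knots live on the 45-degree-rotated lattice: a
#' checkerboard of image sites becomes rectangular in the coordinates
#' `a = (r + c)/2`, `b = (r - c)/2`, so `row_positions`/`col_positions` are
#' interpreted as `a`/`b` knot coordinates and each query `(r, c)` is mapped
#' to `((r + c)/2, (r - c)/2)` before evaluation.
#'
#' Interpolation along each axis uses [interpolate_line()] with the given
#' `kind`, so the result is bicubic Lagrange (`"cubic_poly"`) or a separable
#' natural-spline surface (`"cubic_spline"`), exact at the knots.
#'
#' @param subgrid_values Matrix of knot values, rows indexed by
#'   `row_positions` and columns by `col_positions`.
#' @param row_positions,col_positions Strictly increasing knot coordinates;
#'   default `1..nrow` / `1..ncol`.
#' @param lattice `"rectangular"` or `"quincunx"`.
#' @param query_sites Two-column matrix of query coordinates (`(row, col)`
#'   for rectangular; original image `(r, c)` for quincunx).
#' @param kind `"cubic_poly"` or `"cubic_spline"` (`"linear"` also accepted).
#' @return Numeric vector of interpolated values, one per query row.
#' @export
interpolate_grid <- function(subgrid_values,
                             row_positions = NULL, col_positions = NULL,
                             lattice = c("rectangular", "quincunx"),
                             query_sites,
                             kind = c("cubic_poly", "cubic_spline",
                                      "linear")) {
  lattice <- match.arg(lattice)
  kind <- match.arg(kind)
  if (!is.matrix(subgrid_values))
    .stopf("lattice_error", "'subgrid_values' must be a matrix of knot values")
  if (is.null(row_positions)) row_positions <- seq_len(nrow(subgrid_values))
  if (is.null(col_positions)) col_positions <- seq_len(ncol(subgrid_values))
  if (length(row_positions) != nrow(subgrid_values) ||
      length(col_positions) != ncol(subgrid_values))
    .stopf("lattice_error", "knot coordinates do not match the value grid")
  query_sites <- as.matrix(query_sites)
  if (ncol(query_sites) != 2L)
    .stopf("param_error", "'query_sites' must have two columns")
  qr <- query_sites[, 1]; qc <- query_sites[, 2]
  if (lattice == "quincunx") {
    a <- (qr + qc) / 2; b <- (qr - qc) / 2
    qr <- a; qc <- b
  }
  uqr <- sort(unique(qr)); uqc <- sort(unique(qc))
  tmp <- matrix(0, nrow(subgrid_values), length(uqc))
  for (i in seq_len(nrow(subgrid_values)))
    tmp[i, ] <- interpolate_line(col_positions, subgrid_values[i, ], uqc, kind)
  full <- matrix(0, length(uqr), length(uqc))
  for (j in seq_along(uqc))
    full[, j] <- interpolate_line(row_positions, tmp[, j], uqr, kind)
  full[cbind(match(qr, uqr), match(qc, uqc))]
}
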