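# Channel-independent demosaicing: reconstruct a full six-channel image from
# a mosaic observation with one of five interpolating routines.  Each channel
# is filled using only its own known samples — no cross-channel statistics —
# reflecting the conservative assumption that visible and near-infrared
# content are statistically independent.

.ROUTINES <- c("bilinear_1d", "cubic_poly_1d", "cubic_spline_1d",
               "cubic_poly_2d", "cubic_spline_2d")

#' Demosaicing routine names
#' @return Character vector of the five supported routine identifiers.
#' @export
demosaic_routines <- function() .ROUTINES

#' Specify a demosaicing routine
#'
#' @param routine One of [demosaic_routines()]: `"bilinear_1d"` (piecewise
#'   linear, two-pass separable), `"cubic_poly_1d"` / `"cubic_spline_1d"`
#'   (piecewise 4-point Lagrange cubic / natural cubic spline, two-pass
#'   separable), `"cubic_poly_2d"` / `"cubic_spline_2d"` (tensor-product
#'   bicubic Lagrange / separable natural spline on the channel's sampling
#'   lattice, with checkerboard lattices handled in rotated coordinates).
#' @param boundary Boundary policy; only `"mirror"` (reflection about the end
#'   samples) is supported.
#' @param clamp_output Clamp reconstructed values to `[0,1]` (default
#'   `TRUE`); cubic interpolants can overshoot physical intensity bounds.
#' @return A `demosaic_spec` object.
#' @export
demosaic_spec <- function(routine, boundary = "mirror", clamp_output = TRUE) {
  if (length(routine) != 1L || !routine %in% .ROUTINES)
    .stopf("param_error", "unknown routine '%s' (expected one of %s)",
           paste(routine, collapse = ","), paste(.ROUTINES, collapse = ", "))
  if (!identical(boundary, "mirror"))
    .stopf("param_error", "only the \"mirror\" boundary policy is supported")
  if (!is.logical(clamp_output) || length(clamp_output) != 1L ||
      is.na(clamp_output))
    .stopf("param_error", "'clamp_output' must be TRUE or FALSE")
  structure(list(routine = routine, boundary = boundary,
                 clamp_output = clamp_output),
            class = "demosaic_spec")
}

.routine_kind <- function(routine) {
  switch(routine,
         bilinear_1d = "linear",
         cubic_poly_1d = "cubic_poly",
         cubic_spline_1d = "cubic_spline",
         cubic_poly_2d = "cubic_poly",
         cubic_spline_2d = "cubic_spline")
}

# Two-pass separable 1-D reconstruction: pass 1 interpolates along every row
# that contains known samples of the channel; pass 2 interpolates along
# columns to fill rows that contain none (needed for RGB-IR lattices; a no-op
# for checkerboard channels).
.demosaic_1d <- function(v, k, kind) {
  h <- nrow(v); w <- ncol(v)
  est <- matrix(NA_real_, h, w)
  rows_known <- which(rowSums(k) > 0L)
  for (r in rows_known) {
    kc <- which(k[r, ])
    est[r, ] <- interpolate_line(kc, v[r, kc], seq_len(w), kind)
  }
  rest <- setdiff(seq_len(h), rows_known)
  if (length(rest) > 0L) {
    for (cc in seq_len(w))
      est[rest, cc] <- interpolate_line(rows_known, est[rows_known, cc],
                                        rest, kind)
  }
  est
}

# Classify a channel's known-sample pattern: a rectangular lattice (the
# Cartesian product of its known rows and columns) or a checkerboard
# (quincunx) pattern.  Returns a descriptor or signals a lattice error.
.detect_lattice <- function(k) {
  h <- nrow(k); w <- ncol(k)
  rows <- which(rowSums(k) > 0L)
  cols <- which(colSums(k) > 0L)
  rect <- outer(seq_len(h) %in% rows, seq_len(w) %in% cols, FUN = "&")
  if (identical(as.vector(rect), as.vector(k)))
    return(list(type = "rectangular", rows = rows, cols = cols))
  idx <- which(k, arr.ind = TRUE)
  par <- (idx[, 1] + idx[, 2]) %% 2L
  if (length(unique(par)) == 1L) {
    board <- (outer(seq_len(h), seq_len(w), "+") %% 2L) == par[1]
    if (identical(as.vector(board), as.vector(k)))
      return(list(type = "quincunx", parity0 = (par[1] + 2L) %% 2L))
  }
  .stopf("lattice_error",
         "known samples form neither a rectangular nor a quincunx lattice")
}

.demosaic_2d_rect <- function(v, k, kind, lat) {
  h <- nrow(v); w <- ncol(v)
  rows <- lat$rows; cols <- lat$cols
  tmp <- matrix(0, length(rows), w)
  for (i in seq_along(rows))
    tmp[i, ] <- interpolate_line(cols, v[rows[i], cols], seq_len(w), kind)
  if (length(rows) == h && identical(rows, seq_len(h))) return(tmp)
  est <- matrix(0, h, w)
  for (cc in seq_len(w))
    est[, cc] <- interpolate_line(rows, tmp[, cc], seq_len(h), kind)
  est
}

# Quincunx reconstruction in rotated coordinates.  In a = (r0+c0)/2,
# b = (r0-c0)/2 (0-based pixel coordinates) the checkerboard of known sites
# becomes a rectangular unit lattice; knot values outside the image diamond
# are supplied by mirror reflection of the pixel coordinates, which preserves
# the checkerboard parity.
.demosaic_2d_quincunx <- function(v, k, kind, lat) {
  h <- nrow(v); w <- ncol(v)
  un <- which(!k, arr.ind = TRUE)
  r0 <- un[, 1] - 1L; c0 <- un[, 2] - 1L
  qa <- (r0 + c0) / 2; qb <- (r0 - c0) / 2
  # knot coordinates: a and b are integers shifted by parity/2
  off <- lat$parity0 / 2  # 0 when even sums are known (1-based parity 0)
  # 1-based known parity: (r + c) %% 2 == p1 means 0-based (r0 + c0) even when
  # p1 == 0; knots then sit at integer a, b.  Otherwise at half-integers.
  a_lo <- off + floor(min(qa) - off) - 2
  a_hi <- off + ceiling(max(qa) - off) + 2
  b_lo <- off + floor(min(qb) - off) - 2
  b_hi <- off + ceiling(max(qb) - off) + 2
  a_knots <- seq(a_lo, a_hi, by = 1)
  b_knots <- seq(b_lo, b_hi, by = 1)
  rk <- outer(a_knots, b_knots, "+")       # r0 of each knot
  ck <- outer(a_knots, b_knots, "-")       # c0 of each knot
  ri <- .mirror_index(as.integer(round(rk)) + 1L, h)
  ci <- .mirror_index(as.integer(round(ck)) + 1L, w)
  sub <- matrix(v[cbind(ri, ci)], length(a_knots), length(b_knots))
  est <- matrix(NA_real_, h, w)
  est[un] <- interpolate_grid(sub, a_knots, b_knots, lattice = "quincunx",
                              query_sites = cbind(r0, c0), kind = kind)
  est
}

#' Demosaic a mosaic observation
#'
#' Reconstructs a full six-channel image from a [apply_mosaic()] observation.
#' Known pixels are copied unchanged; unknown pixels of each channel are
#' filled using only that channel's known samples.  Channels with zero known
#' samples (`NIR_2`/`NIR_3` under the RGB-IR sensor) are returned all-`NA`
#' and listed in the `missing_channels` attribute of the result.
#'
#' @param obs A `mosaic_observation`.
#' @param spec A [demosaic_spec()] (a routine name is also accepted).
#' @return A `scene_image` (H x W x 6) with attribute `missing_channels`.
#' @export
demosaic <- function(obs, spec) {
  if (!inherits(obs, "mosaic_observation"))
    .stopf("param_error", "'obs' must come from apply_mosaic()")
  if (is.character(spec)) spec <- demosaic_spec(spec)
  if (!inherits(spec, "demosaic_spec"))
    .stopf("param_error", "'spec' must come from demosaic_spec()")
  d <- dim(obs$values)
  kind <- .routine_kind(spec$routine)
  two_d <- spec$routine %in% c("cubic_poly_2d", "cubic_spline_2d")
  out <- array(NA_real_, d)
  missing <- character(0)
  for (ch in seq_len(6L)) {
    k <- obs$known[, , ch]
    if (!any(k)) {
      missing <- c(missing, .CHANNELS[ch])
      next
    }
    v <- obs$values[, , ch]
    if (all(k)) {
      out[, , ch] <- v
      next
    }
    est <- if (!two_d) {
      .demosaic_1d(v, k, kind)
    } else {
      lat <- .detect_lattice(k)
      if (lat$type == "rectangular") .demosaic_2d_rect(v, k, kind, lat)
      else .demosaic_2d_quincunx(v, k, kind, lat)
    }
    if (spec$clamp_output) est <- .clamp01(est)
    est[k] <- v[k]  # knot fidelity: observed pixels pass through exactly
    out[, , ch] <- est
  }
  out <- .as_scene(out)
  attr(out, "missing_channels") <- missing
  attr(out, "routine") <- spec$routine
  out
}
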