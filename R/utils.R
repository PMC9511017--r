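# Shared internals: channel bookkeeping, error signalling, seeded evaluation,
# Gaussian smoothing, and mirror-boundary separable convolution.

.CHANNELS <- c("VIS_R", "VIS_G", "VIS_B", "NIR_1", "NIR_2", "NIR_3")
.VIS_CHANNELS <- .CHANNELS[1:3]
.NIR_CHANNELS <- .CHANNELS[4:6]

#' Canonical channel order
#'
#' All six-channel images in mosaicbench store their planes in this fixed
#' order: the three visible primaries followed by the three near-infrared
#' "colors" of a stacked-photodiode sensor.
#'
#' @return Character vector `c("VIS_R","VIS_G","VIS_B","NIR_1","NIR_2","NIR_3")`.
#' @export
scene_channels <- function() .CHANNELS

#' Channel groups
#'
#' @param group `"VIS"` or `"NIR"`.
#' @return Character vector of the three channel names in the group.
#' @export
channel_group <- function(group = c("VIS", "NIR")) {
  group <- match.arg(group)
  if (group == "VIS") .VIS_CHANNELS else .NIR_CHANNELS
}

# classed errors so callers/tests can discriminate failure modes
.stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "mosaicbench_error")))
}

.channel_index <- function(channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (any(ch < 1L) || any(ch > 6L))
      .stopf("param_error", "channel index out of range 1..6")
    return(ch)
  }
  idx <- match(channel, .CHANNELS)
  if (anyNA(idx))
    .stopf("param_error", "unknown channel id: %s",
           paste(channel[is.na(idx)], collapse = ", "))
  idx
}

.check_number <- function(x, name, lo = -Inf, hi = Inf,
                          integer = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("param_error", "'%s' must be a single finite number", name)
  if (!allow_inf && !is.finite(x))
    .stopf("param_error", "'%s' must be finite", name)
  if (x < lo || x > hi)
    .stopf("param_error", "'%s' must lie in [%s, %s]", name,
           format(lo), format(hi))
  if (integer && is.finite(x) && x != round(x))
    .stopf("param_error", "'%s' must be an integer", name)
  invisible(x)
}

# run fun() under a given seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  fun()
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.as_scene <- function(a) {
  dimnames(a) <- list(NULL, NULL, .CHANNELS)
  class(a) <- "scene_image"
  a
}

.check_scene <- function(scene, name = "scene") {
  if (!is.array(scene) || length(dim(scene)) != 3L || dim(scene)[3] != 6L)
    .stopf("shape_error", "'%s' must be a height x width x 6 array", name)
  invisible(scene)
}

#' @export
print.scene_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<scene_image> %d x %d pixels, 6 channels (%s)\n",
              d[1], d[2], paste(.CHANNELS, collapse = ", ")))
  rng <- range(x, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

# --- Gaussian smoothing --------------------------------------------------

# Dense separable Gaussian smoother with edge-renormalized weights.  Exact for
# any sigma (including Inf, which degenerates to the image mean); used for the
# synthetic backgrounds and the foreground max-projection where a stationary
# low-pass is all that is needed.
.gauss_weights <- function(n, sigma) {
  if (!is.finite(sigma)) return(matrix(1 / n, n, n))
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-d^2 / (2 * sigma^2))
  w / rowSums(w)
}

.gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  wr <- .gauss_weights(nrow(x), sigma)
  wc <- .gauss_weights(ncol(x), sigma)
  wr %*% x %*% t(wc)
}

# --- Mirror boundary handling -------------------------------------------

# Reflect integer indices into 1..n about the end samples (no edge
# duplication): ..., 3, 2, 1, 2, 3, ..., n-1, n, n-1, ...
.mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  as.integer(j + 1L)
}

# Reflect continuous coordinates into the closed span [lo, hi].
.reflect_into <- function(q, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep(lo, length(q)))
  period <- 2 * span
  t <- (q - lo) %% period
  t <- ifelse(t > span, period - t, t)
  lo + t
}

# Separable convolution with an odd-length 1-D kernel and mirror-extended
# boundaries; the workhorse behind the local SSIM statistics.
.conv_sep_mirror <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- x[.mirror_index((1L - r):(n + r), n),
          .mirror_index((1L - r):(m + r), m), drop = FALSE]
  mr <- matrix(0, n, n + 2L * r)
  mc <- matrix(0, m, m + 2L * r)
  for (j in seq_along(k)) {
    mr[cbind(seq_len(n), seq_len(n) + j - 1L)] <- k[j]
    mc[cbind(seq_len(m), seq_len(m) + j - 1L)] <- k[j]
  }
  mr %*% xp %*% t(mc)
}

.gauss_kernel_1d <- function(width, sigma) {
  if (width %% 2L != 1L)
    .stopf("param_error", "window width must be odd")
  r <- (width - 1L) %/% 2L
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}
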