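# Division-of-focal-plane sensor models: periodic sampling layouts, mosaiced
# observations, and the block-average downsampling used to build
# reduced-resolution ground truth.

#' Build a mosaic sampling layout
#'
#' Describes which channels each pixel of a division-of-focal-plane sensor
#' observes.
#'
#' * `"rgbir"`: one photodiode layer under a 2x2 filter array; each pixel
#'   observes exactly one of `VIS_B`, `VIS_G`, `VIS_R`, `NIR_1` (period
#'   order row 0: B, G / row 1: R, IR before the phase shift), so each of
#'   those four channels is sampled at one quarter of the pixels and
#'   `NIR_2`/`NIR_3` are never observed.
#' * `"bioinspired"`: three stacked photodiode layers under alternating
#'   short-pass/long-pass filters; each pixel observes either all three VIS
#'   channels (short-pass pixel) or all three NIR channels (long-pass
#'   pixel), so every channel is sampled at one half of the pixels.
#'
#' @param architecture `"rgbir"` or `"bioinspired"`.
#' @param variant Bioinspired filter geometry: `"checkerboard"` (default;
#'   short-pass where row+col is even) or `"column_stripes"` (short-pass on
#'   even columns).  Must be omitted for `"rgbir"`.
#' @param phase Integer `(row offset, col offset)` in `{0,1}^2` shifting the
#'   periodic pattern.
#' @return A `mosaic_layout` object.
#' @export
build_mosaic_layout <- function(architecture,
                                variant = NULL,
                                phase = c(0L, 0L)) {
  if (length(architecture) != 1L ||
      !architecture %in% c("rgbir", "bioinspired"))
    .stopf("param_error",
           "unknown architecture '%s' (expected \"rgbir\" or \"bioinspired\")",
           paste(architecture, collapse = ","))
  if (architecture == "rgbir") {
    if (!is.null(variant))
      .stopf("param_error", "'variant' applies only to the bioinspired sensor")
  } else {
    if (is.null(variant)) variant <- "checkerboard"
    if (length(variant) != 1L ||
        !variant %in% c("checkerboard", "column_stripes"))
      .stopf("param_error", "unknown bioinspired variant '%s'",
             paste(variant, collapse = ","))
  }
  if (!is.numeric(phase) || length(phase) != 2L || !all(phase %in% c(0, 1)))
    .stopf("param_error", "'phase' must be a (row, col) offset in {0,1}^2")
  structure(list(architecture = architecture,
                 variant = if (architecture == "bioinspired") variant,
                 phase = as.integer(phase)),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("<mosaic_layout> %s%s, phase (%d, %d)\n", x$architecture,
              if (!is.null(x$variant)) paste0(" / ", x$variant) else "",
              x$phase[1], x$phase[2]))
  invisible(x)
}

#' Known-channel mask implied by a layout
#'
#' Expands the periodic layout to a full boolean mask: entry `(r, c, ch)` is
#' `TRUE` iff channel `ch` is directly observed at pixel `(r, c)`.
#'
#' @param layout A [build_mosaic_layout()] object.
#' @param height,width Image size in pixels.
#' @return A height x width x 6 logical array in [scene_channels()] order.
#' @export
layout_known_mask <- function(layout, height, width) {
  if (!inherits(layout, "mosaic_layout"))
    .stopf("param_error", "'layout' must come from build_mosaic_layout()")
  .check_number(height, "height", lo = 1, integer = TRUE)
  .check_number(width, "width", lo = 1, integer = TRUE)
  rpar <- matrix((seq_len(height) - 1L + layout$phase[1]) %% 2L, height, width)
  cpar <- matrix((seq_len(width) - 1L + layout$phase[2]) %% 2L, height, width,
                 byrow = TRUE)
  known <- array(FALSE, c(height, width, 6L),
                 dimnames = list(NULL, NULL, .CHANNELS))
  if (layout$architecture == "rgbir") {
    known[, , "VIS_B"] <- rpar == 0L & cpar == 0L
    known[, , "VIS_G"] <- rpar == 0L & cpar == 1L
    known[, , "VIS_R"] <- rpar == 1L & cpar == 0L
    known[, , "NIR_1"] <- rpar == 1L & cpar == 1L
  } else {
    shortpass <- if (layout$variant == "checkerboard")
      (rpar + cpar) %% 2L == 0L else cpar == 0L
    for (ch in .VIS_CHANNELS) known[, , ch] <- shortpass
    for (ch in .NIR_CHANNELS) known[, , ch] <- !shortpass
  }
  known
}

#' Sample a scene through a mosaic layout
#'
#' Copies the scene at observed positions and marks everything else unknown.
#' Unknown entries carry `NA` as a sentinel; the boolean `known` mask is
#' authoritative and unknown values must never be read as data.
#'
#' @param scene A six-channel `scene_image`.
#' @param layout A [build_mosaic_layout()] object.
#' @return A `mosaic_observation`: list with `values` (H x W x 6, `NA` where
#'   unobserved), `known` (H x W x 6 logical), and `layout`.
#' @export
apply_mosaic <- function(scene, layout) {
  .check_scene(scene)
  if (!inherits(layout, "mosaic_layout"))
    .stopf("param_error", "'layout' must come from build_mosaic_layout()")
  d <- dim(scene)
  known <- layout_known_mask(layout, d[1], d[2])
  values <- array(as.numeric(scene), d,
                  dimnames = list(NULL, NULL, .CHANNELS))
  values[!known] <- NA_real_
  structure(list(values = values, known = known, layout = layout),
            class = "mosaic_observation")
}

#' @export
print.mosaic_observation <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mosaic_observation> %d x %d pixels, %s sensor\n",
              d[1], d[2], x$layout$architecture))
  dens <- apply(x$known, 3L, mean)
  cat("  per-channel sampling density:",
      paste(sprintf("%s=%.2f", .CHANNELS, dens), collapse = " "), "\n")
  invisible(x)
}

#' Block-average downsampling
#'
#' Replaces each non-overlapping `block` of pixels by its arithmetic mean,
#' per channel — the spatial averaging used to construct a reduced-resolution
#' unmosaiced ground truth from a full-resolution capture.
#'
#' @param image A matrix or H x W x C array; H and W must be divisible by
#'   the block dimensions.
#' @param block Integer `(rows, cols)` block size.
#' @return The downsampled image with the same number of dimensions as the
#'   input.
#' @export
block_average_downsample <- function(image, block = c(2L, 2L)) {
  if (!is.numeric(block) || length(block) != 2L || any(block < 1) ||
      any(block != round(block)))
    .stopf("param_error", "'block' must be two positive integers")
  a <- image
  was_matrix <- is.matrix(a)
  if (was_matrix) dim(a) <- c(dim(a), 1L)
  if (!is.array(a) || length(dim(a)) != 3L)
    .stopf("shape_error", "'image' must be a matrix or 3-d array")
  d <- dim(a); br <- as.integer(block[1]); bc <- as.integer(block[2])
  if (d[1] %% br != 0L || d[2] %% bc != 0L)
    .stopf("shape_error",
           "image size %d x %d is not divisible by block %d x %d",
           d[1], d[2], br, bc)
  h2 <- d[1] %/% br; w2 <- d[2] %/% bc
  dim(a) <- c(br, h2, bc, w2, d[3])
  a <- aperm(a, c(1L, 3L, 2L, 4L, 5L))
  dim(a) <- c(br * bc, h2 * w2 * d[3])
  out <- colMeans(a)
  dim(out) <- c(h2, w2, d[3])
  if (was_matrix) out <- out[, , 1L]
  else if (d[3] == 6L) out <- .as_scene(out)
  out
}
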