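# Fidelity metrics: per-channel absolute errors over the foreground, local
# structural dissimilarity (DSSIM) maps, and CIELAB color differences, each
# summarized by an upper-percentile statistic over the pixels a routine had
# to interpolate.

#' Metric configuration
#'
#' @param percentile Upper quantile summarizing the DSSIM and color-difference
#'   maps (default 0.99: the 99th percentile acts as an upper bound so that
#'   rare, clinically relevant pixels are not averaged away).
#' @param ssim_window Odd window width in pixels for the local SSIM
#'   statistics (default 11).
#' @param ssim_sigma Gaussian weighting sigma of the SSIM window (default
#'   1.5 px).
#' @param ssim_k1,ssim_k2 SSIM stabilization constants (0.01, 0.03).
#' @param dynamic_range Intensity dynamic range `L` (1 for normalized
#'   images).
#' @param delta_e_formula `"cie76"` (Euclidean CIELAB distance; default) or
#'   `"ciede2000"`.
#' @param jnd Just-noticeable color difference; pixels with a color
#'   difference strictly above this are flagged perceptible (default 1.00).
#' @return A `metric_config` object.
#' @export
metric_config <- function(percentile = 0.99,
                          ssim_window = 11L, ssim_sigma = 1.5,
                          ssim_k1 = 0.01, ssim_k2 = 0.03,
                          dynamic_range = 1.0,
                          delta_e_formula = c("cie76", "ciede2000"),
                          jnd = 1.00) {
  delta_e_formula <- match.arg(delta_e_formula)
  .check_number(percentile, "percentile", lo = 1e-12, hi = 1)
  .check_number(ssim_window, "ssim_window", lo = 3, integer = TRUE)
  if (ssim_window %% 2L != 1L)
    .stopf("param_error", "'ssim_window' must be odd")
  .check_number(ssim_sigma, "ssim_sigma", lo = 1e-9)
  .check_number(ssim_k1, "ssim_k1", lo = 0)
  .check_number(ssim_k2, "ssim_k2", lo = 0)
  .check_number(dynamic_range, "dynamic_range", lo = 1e-9)
  .check_number(jnd, "jnd", lo = 0)
  structure(list(percentile = percentile,
                 ssim_window = as.integer(ssim_window),
                 ssim_sigma = ssim_sigma,
                 ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 dynamic_range = dynamic_range,
                 delta_e_formula = delta_e_formula,
                 jnd = jnd),
            class = "metric_config")
}

#' Foreground mask
#'
#' Restricts all fidelity statistics to the part of the frame that carries
#' scene content.  The mask thresholds the per-pixel maximum over
#' Gaussian-smoothed channels, either at a fixed intensity `tau` or at an
#' Otsu threshold of that max-projection.
#'
#' @param scene A six-channel `scene_image`.
#' @param method `"fixed"` or `"otsu"` (the latter uses `EBImage::otsu`).
#' @param tau Fixed intensity threshold (ignored for `"otsu"`).
#' @param smooth_sigma Gaussian sigma (pixels) applied per channel before the
#'   max-projection.
#' @return A `foreground_mask`: list with logical `mask`, `method`, `tau`.
#' @export
compute_foreground_mask <- function(scene, method = c("fixed", "otsu"),
                                    tau = 0.02, smooth_sigma = 2) {
  method <- match.arg(method)
  .check_scene(scene)
  .check_number(tau, "tau", lo = 0)
  .check_number(smooth_sigma, "smooth_sigma", lo = 0)
  maxproj <- matrix(-Inf, dim(scene)[1], dim(scene)[2])
  for (ch in seq_len(6L)) {
    sm <- .gauss_smooth(scene[, , ch], smooth_sigma)
    maxproj <- pmax(maxproj, sm)
  }
  if (method == "otsu") {
    if (!requireNamespace("EBImage", quietly = TRUE))
      .stopf("param_error",
             "method = \"otsu\" requires the EBImage package")
    tau <- as.numeric(EBImage::otsu(.clamp01(maxproj), range = c(0, 1)))
  }
  mask <- maxproj > tau
  if (!any(mask))
    .stopf("degenerate_mask_error", "foreground mask is empty at tau = %g", tau)
  structure(list(mask = mask, method = method, tau = tau),
            class = "foreground_mask")
}

.check_fg <- function(fg, d) {
  if (!inherits(fg, "foreground_mask"))
    .stopf("param_error", "'fg' must come from compute_foreground_mask()")
  if (!all(dim(fg$mask) == d[1:2]))
    .stopf("shape_error", "foreground mask does not match the image size")
}

.channel_plane <- function(img, ch) {
  p <- img[, , ch]
  if (all(is.na(p))) NULL else p
}

#' Sum of absolute errors over the foreground
#'
#' `SAE = sum over foreground pixels of |est - ref|` for one channel, taken
#' over all foreground pixels so that it reflects both the vanishing error
#' at directly observed pixels and the interpolation error elsewhere.
#'
#' @param ref,est Six-channel `scene_image`s of equal size.
#' @param fg A [compute_foreground_mask()] object.
#' @param channel Channel id (name or index).
#' @return The SAE (>= 0), or `NA` if the channel is absent from `est`.
#' @export
sum_absolute_error <- function(ref, est, fg, channel) {
  .check_scene(ref, "ref"); .check_scene(est, "est")
  if (!all(dim(ref) == dim(est)))
    .stopf("shape_error", "'ref' and 'est' differ in shape")
  .check_fg(fg, dim(ref))
  ch <- .channel_index(channel)
  e <- .channel_plane(est, ch)
  if (is.null(e)) return(NA_real_)
  sum(abs(e - ref[, , ch])[fg$mask])
}

#' Mean absolute error over unknown foreground pixels
#'
#' `MAE = mean over {foreground and not known} of |est - ref|` for one
#' channel: the error attributable to the demosaicing routine alone, since
#' directly observed pixels are excluded.
#'
#' @inheritParams sum_absolute_error
#' @param known H x W x 6 logical array of directly observed entries
#'   (`mosaic_observation$known`).
#' @return The MAE (>= 0), or `NA` if the channel is absent from `est`.
#' @export
mean_absolute_error <- function(ref, est, fg, known, channel) {
  .check_scene(ref, "ref"); .check_scene(est, "est")
  if (!all(dim(ref) == dim(est)))
    .stopf("shape_error", "'ref' and 'est' differ in shape")
  .check_fg(fg, dim(ref))
  if (!is.array(known) || !all(dim(known) == dim(ref)))
    .stopf("shape_error", "'known' must be an H x W x 6 logical array")
  ch <- .channel_index(channel)
  e <- .channel_plane(est, ch)
  if (is.null(e)) return(NA_real_)
  sel <- fg$mask & !known[, , ch]
  if (!any(sel))
    .stopf("degenerate_mask_error",
           "no unknown foreground pixels for channel %s", .CHANNELS[ch])
  mean(abs(e - ref[, , ch])[sel])
}

# local SSIM map between two planes (Gaussian window, mirror boundaries)
.ssim_map <- function(x, y, cfg) {
  if (cfg$ssim_window > min(dim(x)))
    .stopf("param_error", "SSIM window is larger than the image")
  k <- .gauss_kernel_1d(cfg$ssim_window, cfg$ssim_sigma)
  mu_x <- .conv_sep_mirror(x, k)
  mu_y <- .conv_sep_mirror(y, k)
  sxx <- .conv_sep_mirror(x * x, k) - mu_x^2
  syy <- .conv_sep_mirror(y * y, k) - mu_y^2
  sxy <- .conv_sep_mirror(x * y, k) - mu_x * mu_y
  c1 <- (cfg$ssim_k1 * cfg$dynamic_range)^2
  c2 <- (cfg$ssim_k2 * cfg$dynamic_range)^2
  ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
}

.group_channels <- function(est, group) {
  idx <- .channel_index(channel_group(group))
  avail <- idx[vapply(idx, function(i) !all(is.na(est[, , i])), logical(1))]
  list(all = idx, avail = avail)
}

.group_unknown_any <- function(known, idx) {
  anyunk <- matrix(FALSE, dim(known)[1], dim(known)[2])
  for (i in idx) anyunk <- anyunk | !known[, , i]
  anyunk
}

.percentile_stat <- function(map, sel, cfg) {
  if (!any(sel))
    .stopf("degenerate_mask_error", "no unknown foreground pixels to evaluate")
  as.numeric(stats::quantile(map[sel], cfg$percentile, type = 7,
                             names = FALSE))
}

#' Structural dissimilarity statistic for a spectral group
#'
#' Computes per-channel local SSIM maps (Gaussian window, dynamic range `L`),
#' converts them to DSSIM `(1 - SSIM)/2` in `[0,1]`, pools the group's
#' available channels by per-pixel mean (under the RGB-IR sensor the NIR
#' group contains `NIR_1` only), and summarizes the pooled map by
#' `cfg$percentile` over the foreground pixels where at least one group
#' channel was interpolated.
#'
#' @inheritParams mean_absolute_error
#' @param group `"VIS"` or `"NIR"`.
#' @param cfg A [metric_config()].
#' @return A list with `map` (pooled H x W DSSIM), `statistic`, `defined`
#'   (`TRUE`), `channels` (pooled channel names) and `n` (evaluated pixels).
#' @export
dssim_statistic <- function(ref, est, group = c("VIS", "NIR"), fg, known,
                            cfg = metric_config()) {
  group <- match.arg(group)
  .check_scene(ref, "ref"); .check_scene(est, "est")
  .check_fg(fg, dim(ref))
  gr <- .group_channels(est, group)
  if (length(gr$avail) == 0L)
    .stopf("coverage_error", "no %s channel present in the estimate", group)
  maps <- lapply(gr$avail, function(i)
    (1 - .ssim_map(ref[, , i], est[, , i], cfg)) / 2)
  pooled <- Reduce(`+`, maps) / length(maps)
  pooled <- pmin(pmax(pooled, 0), 1)  # guard float spill outside [0,1]
  sel <- fg$mask & .group_unknown_any(known, gr$avail)
  stat <- .percentile_stat(pooled, sel, cfg)
  list(map = pooled, statistic = stat, defined = TRUE,
       channels = .CHANNELS[gr$avail], n = sum(sel))
}

#' Convert intensity triplets to CIELAB
#'
#' Triplets are treated as linear RGB with sRGB primaries under D65 (no
#' transfer-function gamma, since the pipeline works in linear intensity),
#' converted through XYZ to CIELAB with the white point defined so that
#' `(1,1,1)` maps exactly to `L* = 100, a* = b* = 0`.
#'
#' @param triplet Length-3 vector or N x 3 matrix of intensities.
#' @return Matrix (or vector) of `(L*, a*, b*)` coordinates.
#' @export
triplet_to_lab <- function(triplet) {
  vec_in <- is.null(dim(triplet))
  rgb <- if (vec_in) matrix(triplet, ncol = 3L) else as.matrix(triplet)
  if (ncol(rgb) != 3L)
    .stopf("param_error", "'triplet' must have three components")
  m <- rbind(c(0.41239080, 0.35758434, 0.18048079),
             c(0.21263901, 0.71516868, 0.07219232),
             c(0.01933082, 0.11919478, 0.95053215))
  xyz <- rgb %*% t(m)
  white <- rowSums(m)  # image of (1,1,1): the adopted white point
  eps <- (6 / 29)^3
  f <- function(t) ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1] / white[1])
  fy <- f(xyz[, 2] / white[2])
  fz <- f(xyz[, 3] / white[3])
  lab <- cbind(L = 116 * fy - 16,
               a = 500 * (fx - fy),
               b = 200 * (fy - fz))
  if (vec_in) drop(lab) else lab
}

# CIEDE2000 color difference (kL = kC = kH = 1), vectorized over row pairs.
.ciede2000 <- function(lab1, lab2) {
  l1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  l2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  c1 <- sqrt(a1^2 + b1^2); c2 <- sqrt(a2^2 + b2^2)
  cbar <- (c1 + c2) / 2
  g <- 0.5 * (1 - sqrt(cbar^7 / (cbar^7 + 25^7)))
  a1p <- (1 + g) * a1; a2p <- (1 + g) * a2
  c1p <- sqrt(a1p^2 + b1^2); c2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(c1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(c2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
  dlp <- l2 - l1
  dcp <- c2p - c1p
  dh <- h2p - h1p
  dh <- ifelse(c1p * c2p == 0, 0,
               ifelse(dh > 180, dh - 360, ifelse(dh < -180, dh + 360, dh)))
  dhp <- 2 * sqrt(c1p * c2p) * sin(dh / 2 * pi / 180)
  lbar <- (l1 + l2) / 2
  cbarp <- (c1p + c2p) / 2
  hsum <- h1p + h2p
  hbar <- ifelse(c1p * c2p == 0, hsum,
                 ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                        ifelse(hsum < 360, (hsum + 360) / 2,
                               (hsum - 360) / 2)))
  t <- 1 - 0.17 * cos((hbar - 30) * pi / 180) +
    0.24 * cos(2 * hbar * pi / 180) +
    0.32 * cos((3 * hbar + 6) * pi / 180) -
    0.20 * cos((4 * hbar - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbar - 275) / 25)^2)
  rc <- 2 * sqrt(cbarp^7 / (cbarp^7 + 25^7))
  sl <- 1 + 0.015 * (lbar - 50)^2 / sqrt(20 + (lbar - 50)^2)
  sc <- 1 + 0.045 * cbarp
  sh <- 1 + 0.015 * cbarp * t
  rt <- -sin(2 * dtheta * pi / 180) * rc
  sqrt((dlp / sl)^2 + (dcp / sc)^2 + (dhp / sh)^2 +
         rt * (dcp / sc) * (dhp / sh))
}

.perceptible <- function(map, jnd) map > jnd

#' Color-difference statistic for a spectral group
#'
#' Converts the group's channel triplet of `ref` and `est` to CIELAB (NIR
#' triplets use the false-color assignment `NIR_1/2/3` to the first, second
#' and third primary), computes the per-pixel color difference with the
#' configured formula, and summarizes it by `cfg$percentile` over the
#' foreground pixels where at least one group channel was interpolated.
#'
#' The statistic requires all three group channels: under the RGB-IR sensor
#' the NIR group has only one channel, so the statistic is undefined there
#' and the result carries `defined = FALSE` with an `NA` statistic (rendered
#' as a dash in reports).
#'
#' @inheritParams dssim_statistic
#' @return A list with `map` (H x W color difference), `statistic`,
#'   `defined`, `perceptible` (logical map of differences strictly above
#'   `cfg$jnd`) and `n`; when undefined, `map`/`perceptible` are `NULL` and
#'   `statistic` is `NA`.
#' @export
delta_e_statistic <- function(ref, est, group = c("VIS", "NIR"), fg, known,
                              cfg = metric_config()) {
  group <- match.arg(group)
  .check_scene(ref, "ref"); .check_scene(est, "est")
  .check_fg(fg, dim(ref))
  gr <- .group_channels(est, group)
  if (length(gr$avail) < 3L)
    return(list(map = NULL, statistic = NA_real_, defined = FALSE,
                perceptible = NULL, n = 0L))
  idx <- gr$all
  d <- dim(ref)
  ref_t <- matrix(ref[, , idx], ncol = 3L)
  est_t <- matrix(est[, , idx], ncol = 3L)
  lab_ref <- triplet_to_lab(ref_t)
  lab_est <- triplet_to_lab(est_t)
  de <- if (cfg$delta_e_formula == "cie76")
    sqrt(rowSums((lab_ref - lab_est)^2))
  else .ciede2000(lab_ref, lab_est)
  map <- matrix(de, d[1], d[2])
  sel <- fg$mask & .group_unknown_any(known, idx)
  stat <- .percentile_stat(map, sel, cfg)
  list(map = map, statistic = stat, defined = TRUE,
       perceptible = .perceptible(map, cfg$jnd), n = sum(sel))
}
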