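# Synthetic six-channel surgical scenes and analytic fixtures.
#
# The generator emulates the content of a fluorescence image-guided surgery
# field: a smooth tissue-colored visible background crossed by darker
# vessel-like curves, and sparse bright fluorescent blobs in the
# near-infrared channels.  The visible and near-infrared groups are drawn
# from independent random substreams, reflecting the conservative modelling
# assumption that reflectance and fluorescence carry statistically
# independent information.

#' Parameters for the synthetic scene generator
#'
#' Bundles every knob of the scene model together with the seed, so that a
#' parameter set fully determines the generated image.
#'
#' @param seed Integer seed; identical parameter sets (including the seed)
#'   produce bit-identical scenes.
#' @param height,width Image size in pixels (at least 16 each).
#' @param vis_base_color Length-3 vector in `[0,1]`: the mean linear-RGB
#'   tissue color of the visible background.
#' @param background_smoothness Correlation scale (pixels) of the visible
#'   background texture: a two-octave Gaussian random field with a coarse
#'   component at this sigma and a fine component at one sixth of it, so the
#'   background carries both organ-scale and pixel-scale structure.  `Inf`
#'   yields a perfectly flat background.
#' @param n_vessels Number of vessel-like curves rendered into the visible
#'   channels (random cubic Bezier curves with a Gaussian cross-profile,
#'   darkening the background multiplicatively to 0.6 at their centerline).
#' @param vessel_width_sigma Gaussian cross-profile sigma of the vessels
#'   (pixels).
#' @param n_blobs Number of fluorescent blobs rendered into the NIR channels.
#' @param blob_sigma_range Length-2 vector (pixels): blob radii are drawn
#'   uniformly from this range.
#' @param blob_amplitude_range Length-2 vector in `[0,1]`: blob peak
#'   amplitudes are drawn uniformly from this range.
#' @param nir_crosstalk 3x3 non-negative mixing matrix with rows summing to
#'   at most 1; row `k` distributes a class-`k` blob across the three NIR
#'   channels, emulating a fluorophore's emission split across the stacked
#'   photodiode layers.
#' @param noise_gain Signal-dependent (shot) noise gain used by
#'   [add_sensor_noise()]; dimensionless.
#' @param read_noise_sigma Signal-independent read-noise standard deviation
#'   (intensity units).
#'
#' @return An object of class `synth_params`.
#' @seealso [generate_scene()], [add_sensor_noise()]
#' @export
synth_params <- function(seed = 1L,
                         height = 256L, width = 256L,
                         vis_base_color = c(0.55, 0.30, 0.25),
                         background_smoothness = 8,
                         n_vessels = 6L, vessel_width_sigma = 1.5,
                         n_blobs = 5L,
                         blob_sigma_range = c(3, 8),
                         blob_amplitude_range = c(0.4, 0.9),
                         nir_crosstalk = default_nir_crosstalk(),
                         noise_gain = 4e-5,
                         read_noise_sigma = 0.001) {
  .check_number(seed, "seed", integer = TRUE)
  .check_number(height, "height", lo = 16, integer = TRUE)
  .check_number(width, "width", lo = 16, integer = TRUE)
  if (!is.numeric(vis_base_color) || length(vis_base_color) != 3L ||
      any(!is.finite(vis_base_color)) ||
      any(vis_base_color < 0) || any(vis_base_color > 1))
    .stopf("param_error", "'vis_base_color' must be a 3-vector in [0,1]")
  .check_number(background_smoothness, "background_smoothness", lo = 0,
                allow_inf = TRUE)
  .check_number(n_vessels, "n_vessels", lo = 0, integer = TRUE)
  .check_number(vessel_width_sigma, "vessel_width_sigma", lo = 1e-6)
  .check_number(n_blobs, "n_blobs", lo = 0, integer = TRUE)
  if (!is.numeric(blob_sigma_range) || length(blob_sigma_range) != 2L ||
      any(blob_sigma_range <= 0) || diff(blob_sigma_range) < 0)
    .stopf("param_error", "'blob_sigma_range' must be a positive (min,max) pair")
  if (!is.numeric(blob_amplitude_range) || length(blob_amplitude_range) != 2L ||
      any(blob_amplitude_range < 0) || any(blob_amplitude_range > 1) ||
      diff(blob_amplitude_range) < 0)
    .stopf("param_error",
           "'blob_amplitude_range' must be a (min,max) pair in [0,1]")
  if (!is.matrix(nir_crosstalk) || !all(dim(nir_crosstalk) == c(3L, 3L)) ||
      any(nir_crosstalk < 0) || any(rowSums(nir_crosstalk) > 1 + 1e-12))
    .stopf("param_error",
           "'nir_crosstalk' must be a non-negative 3x3 matrix with row sums <= 1")
  .check_number(noise_gain, "noise_gain", lo = 0)
  .check_number(read_noise_sigma, "read_noise_sigma", lo = 0)
  structure(list(seed = as.integer(seed),
                 height = as.integer(height), width = as.integer(width),
                 vis_base_color = as.numeric(vis_base_color),
                 background_smoothness = background_smoothness,
                 n_vessels = as.integer(n_vessels),
                 vessel_width_sigma = vessel_width_sigma,
                 n_blobs = as.integer(n_blobs),
                 blob_sigma_range = as.numeric(blob_sigma_range),
                 blob_amplitude_range = as.numeric(blob_amplitude_range),
                 nir_crosstalk = nir_crosstalk,
                 noise_gain = noise_gain,
                 read_noise_sigma = read_noise_sigma),
            class = "synth_params")
}

#' Default NIR crosstalk matrix
#'
#' Diagonal-dominant mixing: each fluorescent blob deposits 80% of its
#' amplitude in its own NIR channel and 10% in each of the other two.
#'
#' @return A 3x3 numeric matrix.
#' @export
default_nir_crosstalk <- function() {
  matrix(c(0.8, 0.1, 0.1,
           0.1, 0.8, 0.1,
           0.1, 0.1, 0.8), 3L, 3L, byrow = TRUE)
}

# internal texture gains: convert the smoothed unit-noise fields into a
# relative modulation of the base color.  The background is a two-octave
# field — a coarse component at sigma = background_smoothness and a fine
# component at sigma/6 — because tissue carries structure at pixel scale as
# well as at organ scale; both octaves flatten together as the smoothness
# grows.
.TEXTURE_GAIN_COARSE <- 1.05
.TEXTURE_GAIN_FINE <- 0.45
.VESSEL_DARKENING <- 0.4      # centerline factor 1 - 0.4 = 0.6
.NIR_UPTAKE_GAIN <- 2         # heterogeneous fluorophore uptake modulation
.NIR_UPTAKE_SIGMA <- 1.5      # pixels
.NIR_GLOW_GAIN <- 0.6         # diffuse scattering halo around blobs
.NIR_GLOW_SIGMA <- 12         # pixels

.render_vis <- function(params) {
  h <- params$height; w <- params$width
  zc <- matrix(stats::rnorm(h * w), h, w)
  zc <- .gauss_smooth(zc, params$background_smoothness)
  zf <- matrix(stats::rnorm(h * w), h, w)
  zf <- .gauss_smooth(zf, params$background_smoothness / 6)
  tex <- .TEXTURE_GAIN_COARSE * (zc - mean(zc)) +
    .TEXTURE_GAIN_FINE * (zf - mean(zf))
  vis <- array(0, c(h, w, 3L))
  for (k in 1:3)
    vis[, , k] <- params$vis_base_color[k] * (1 + tex)
  if (params$n_vessels > 0L) {
    canvas <- matrix(0, h, w)
    npts <- 4L * max(h, w)
    tt <- seq(0, 1, length.out = npts)
    b0 <- (1 - tt)^3; b1 <- 3 * (1 - tt)^2 * tt
    b2 <- 3 * (1 - tt) * tt^2; b3 <- tt^3
    for (v in seq_len(params$n_vessels)) {
      pr <- stats::runif(4L, 1, h)
      pc <- stats::runif(4L, 1, w)
      rr <- round(b0 * pr[1] + b1 * pr[2] + b2 * pr[3] + b3 * pr[4])
      cc <- round(b0 * pc[1] + b1 * pc[2] + b2 * pc[3] + b3 * pc[4])
      keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      canvas[cbind(rr[keep], cc[keep])] <- 1
    }
    prof <- .gauss_smooth(canvas, params$vessel_width_sigma)
    mx <- max(prof)
    if (mx > 0) {
      prof <- prof / mx
      factor <- 1 - .VESSEL_DARKENING * prof
      for (k in 1:3) vis[, , k] <- vis[, , k] * factor
    }
  }
  vis
}

.render_nir <- function(params) {
  h <- params$height; w <- params$width
  nir <- array(0, c(h, w, 3L))
  if (params$n_blobs > 0L) {
    rows <- seq_len(h); cols <- seq_len(w)
    for (b in seq_len(params$n_blobs)) {
      r0 <- stats::runif(1L, 1, h)
      c0 <- stats::runif(1L, 1, w)
      sig <- stats::runif(1L, params$blob_sigma_range[1],
                          params$blob_sigma_range[2])
      amp <- stats::runif(1L, params$blob_amplitude_range[1],
                          params$blob_amplitude_range[2])
      cls <- sample.int(3L, 1L)
      g <- exp(-outer((rows - r0)^2, (cols - c0)^2, "+") / (2 * sig^2))
      for (j in 1:3)
        nir[, , j] <- nir[, , j] + amp * params$nir_crosstalk[cls, j] * g
    }
    # diffuse scattering halo: tissue spreads part of the emission into a dim
    # glow around each blob (zero when there is no blob signal)
    for (j in 1:3)
      nir[, , j] <- nir[, , j] +
        .NIR_GLOW_GAIN * .gauss_smooth(nir[, , j], .NIR_GLOW_SIGMA)
    # heterogeneous fluorophore uptake and scattering: shared pixel-scale
    # modulation of the emission field
    zu <- matrix(stats::rnorm(h * w), h, w)
    zu <- .gauss_smooth(zu, .NIR_UPTAKE_SIGMA)
    uptake <- pmax(1 + .NIR_UPTAKE_GAIN * (zu - mean(zu)), 0)
    for (j in 1:3) nir[, , j] <- nir[, , j] * uptake
  }
  nir
}

#' Generate a synthetic six-channel scene
#'
#' Renders the visible channels (smoothed random field around the base tissue
#' color, darkened along vessel-like curves) and the near-infrared channels
#' (zero background plus Gaussian fluorescent blobs mixed across the three
#' NIR channels).  The two groups are drawn from independent random
#' substreams derived from `params$seed`, so VIS and NIR content are
#' statistically independent across seeds.  No sensor noise is added here;
#' see [add_sensor_noise()].
#'
#' @param params A [synth_params()] object.
#' @return A `scene_image`: height x width x 6 array with all values in
#'   `[0,1]`, channels in [scene_channels()] order.
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "synth_params"))
    .stopf("param_error", "'params' must come from synth_params()")
  vis_seed <- params$seed %% 2147483647
  nir_seed <- (params$seed + 1000003) %% 2147483647
  vis <- .with_seed(vis_seed, function() .render_vis(params))
  nir <- .with_seed(nir_seed, function() .render_nir(params))
  scene <- array(0, c(params$height, params$width, 6L))
  scene[, , 1:3] <- vis
  scene[, , 4:6] <- nir
  .as_scene(.clamp01(scene))
}

#' Polynomial ramp fixture
#'
#' Every channel equals the same polynomial of a single pixel coordinate,
#' rescaled to `[0,1]`: `((t - t_min)/(t_max - t_min))^degree` where `t` is
#' the row, column, or row+column (diagonal) coordinate.  Degree 0 yields a
#' constant image at 0.5.  These fixtures make interpolator exactness
#' directly checkable: a degree-p interpolating routine must reproduce a
#' degree-<=p ramp in interior regions.
#'
#' @param height,width Image size in pixels.
#' @param axis `"row"`, `"column"`, or `"diagonal"`: the coordinate the ramp
#'   varies along.
#' @param degree Polynomial degree; one of 0, 1, 3.
#' @return A `scene_image` with six identical channels.
#' @export
generate_ramp_fixture <- function(height, width,
                                  axis = c("column", "row", "diagonal"),
                                  degree = 1) {
  axis <- match.arg(axis)
  .check_number(height, "height", lo = 2, integer = TRUE)
  .check_number(width, "width", lo = 2, integer = TRUE)
  if (!degree %in% c(0, 1, 3))
    .stopf("param_error", "'degree' must be one of 0, 1, 3")
  t <- switch(axis,
              row = matrix((seq_len(height) - 1) / (height - 1), height, width),
              column = matrix((seq_len(width) - 1) / (width - 1), height, width,
                              byrow = TRUE),
              diagonal = outer(seq_len(height) - 1, seq_len(width) - 1, "+") /
                (height + width - 2))
  plane <- if (degree == 0) matrix(0.5, height, width) else t^degree
  scene <- array(rep(plane, 6L), c(height, width, 6L))
  .as_scene(scene)
}

#' Two-point-source fixture
#'
#' Renders two identical Gaussian spots in one channel, centered
#' symmetrically about the image center and separated along the row
#' direction (i.e. displaced in column); all other channels are zero.  At
#' the resolution limit the profile through the two sources shows two
#' intensity maxima and one minimum between them — three extrema in total —
#' which this fixture makes countable.
#'
#' @param height,width Image size in pixels.
#' @param separation Center-to-center spot distance in pixels (>= 0).
#' @param sigma Gaussian spot sigma in pixels (> 0).
#' @param channel Channel id (name from [scene_channels()] or index 1..6)
#'   receiving the spots.
#' @return A `scene_image`, mirror-symmetric about the vertical centerline.
#' @export
generate_point_pair <- function(height, width, separation, sigma,
                                channel = "NIR_1") {
  .check_number(height, "height", lo = 4, integer = TRUE)
  .check_number(width, "width", lo = 4, integer = TRUE)
  .check_number(separation, "separation", lo = 0)
  .check_number(sigma, "sigma", lo = 1e-9)
  ch <- .channel_index(channel)
  r0 <- (height + 1) / 2
  cc <- (width + 1) / 2 + c(-1, 1) * separation / 2
  if (any(cc < 1) || any(cc > width))
    .stopf("param_error", "point sources fall outside the image")
  rows <- seq_len(height); cols <- seq_len(width)
  g <- exp(-outer((rows - r0)^2, (cols - cc[1])^2, "+") / (2 * sigma^2)) +
    exp(-outer((rows - r0)^2, (cols - cc[2])^2, "+") / (2 * sigma^2))
  scene <- array(0, c(height, width, 6L))
  scene[, , ch] <- .clamp01(0.5 * g)
  .as_scene(scene)
}

#' Add signal-dependent sensor noise
#'
#' Replaces each intensity `x` by `x + N(0, noise_gain * x +
#' read_noise_sigma^2)`, clamped to `[0,1]` — a Gaussian approximation of
#' Poisson shot noise plus additive read noise.
#'
#' @param scene A six-channel `scene_image` (or any numeric array).
#' @param noise_gain Shot-noise variance per unit intensity (>= 0).
#' @param read_noise_sigma Read-noise standard deviation (>= 0).
#' @param seed Integer seed; the operation is deterministic given the seed.
#' @return A noisy `scene_image` of the same shape.
#' @export
add_sensor_noise <- function(scene, noise_gain, read_noise_sigma, seed) {
  .check_scene(scene)
  .check_number(noise_gain, "noise_gain", lo = 0)
  .check_number(read_noise_sigma, "read_noise_sigma", lo = 0)
  .check_number(seed, "seed", integer = TRUE)
  if (noise_gain == 0 && read_noise_sigma == 0) return(.as_scene(scene))
  noisy <- .with_seed(seed, function() {
    sd <- sqrt(noise_gain * pmax(scene, 0) + read_noise_sigma^2)
    scene + stats::rnorm(length(scene), mean = 0, sd = sd)
  })
  .as_scene(.clamp01(noisy))
}
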