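# Fidelity metrics: foreground masks, absolute errors, DSSIM, CIELAB color
# differences.

test_that("foreground masks behave on bright, dark, and blob scenes", {
  bright <- mosaicbench:::.as_scene(array(0.8, c(24, 24, 6)))
  fg <- compute_foreground_mask(bright, tau = 0.02)
  expect_true(all(fg$mask))
  dark <- mosaicbench:::.as_scene(array(0, c(24, 24, 6)))
  expect_error(compute_foreground_mask(dark, tau = 0.02),
               class = "degenerate_mask_error")
  # a single Gaussian blob: mask area close to the analytic support at the
  # threshold radius (accounting for the pre-smoothing of the projection)
  h <- 64; sig <- 6; amp <- 0.8; smooth <- 1
  s <- array(0, c(h, h, 6))
  rows <- seq_len(h)
  s[, , 4] <- amp * exp(-outer((rows - 32)^2, (rows - 32)^2, "+") /
                          (2 * sig^2))
  s <- mosaicbench:::.as_scene(s)
  sig_eff <- sqrt(sig^2 + smooth^2)
  amp_eff <- amp * sig^2 / sig_eff^2
  tau <- amp_eff * exp(-2)  # cuts the smoothed blob at radius 2*sig_eff
  fg <- compute_foreground_mask(s, tau = tau, smooth_sigma = smooth)
  analytic <- pi * (2 * sig_eff)^2
  expect_lt(abs(sum(fg$mask) - analytic) / analytic, 0.2)
})

test_that("otsu foreground thresholding separates a bimodal scene", {
  skip_if_not_installed("EBImage")
  s <- array(0.05, c(32, 32, 6))
  s[9:24, 9:24, ] <- 0.8
  s <- mosaicbench:::.as_scene(s)
  fg <- compute_foreground_mask(s, method = "otsu", smooth_sigma = 0)
  expect_gt(fg$tau, 0.05)
  expect_lt(fg$tau, 0.8)
  expect_true(all(fg$mask[12:21, 12:21]))
  expect_false(any(fg$mask[1:4, 1:4]))
})

test_that("SAE and MAE follow their definitions", {
  ref <- mosaicbench:::.as_scene(array(0.5, c(2, 2, 6)))
  est <- ref
  est[1, 2, 1] <- 0.25; est[2, 1, 1] <- 0.75
  fg <- structure(list(mask = matrix(TRUE, 2, 2), method = "fixed",
                       tau = 0), class = "foreground_mask")
  expect_equal(sum_absolute_error(ref, est, fg, "VIS_R"), 0.5)
  expect_equal(sum_absolute_error(ref, ref, fg, "VIS_R"), 0)
  known <- array(FALSE, c(2, 2, 6))
  known[1, 1, 1] <- TRUE
  est2 <- ref
  est2[1, 2, 1] <- 0.6; est2[2, 1, 1] <- 0.8  # errors 0.1 and 0.3
  known2 <- known
  known2[2, 2, 1] <- TRUE
  expect_equal(mean_absolute_error(ref, est2, fg, known2, "VIS_R"), 0.2)
  # known pixels never contribute, whatever their est value
  est3 <- est2
  est3[1, 1, 1] <- 0
  expect_equal(mean_absolute_error(ref, est3, fg, known2, "VIS_R"), 0.2)
  expect_error(mean_absolute_error(ref, est2, fg,
                                   array(TRUE, c(2, 2, 6)), "VIS_R"),
               class = "degenerate_mask_error")
})

test_that("SAE equals MAE times the unknown foreground count under copy-at-known", {
  s <- generate_scene(small_params(seed = 12, h = 32, w = 32))
  fg <- compute_foreground_mask(s)
  for (arch in c("rgbir", "bioinspired")) {
    obs <- apply_mosaic(s, build_mosaic_layout(arch))
    est <- demosaic(obs, "cubic_poly_1d")
    for (ch in c("VIS_G", "NIR_1")) {
      n_unknown <- sum(fg$mask & !obs$known[, , ch])
      sae <- sum_absolute_error(s, est, fg, ch)
      mae <- mean_absolute_error(s, est, fg, obs$known, ch)
      expect_equal(sae, mae * n_unknown, tolerance = 1e-12)
    }
  }
})

test_that("DSSIM is zero at equality, bounded, and matches its closed form", {
  s <- generate_scene(small_params(seed = 5, h = 32, w = 32))
  fg <- compute_foreground_mask(s)
  obs <- apply_mosaic(s, build_mosaic_layout("bioinspired"))
  cfg <- metric_config()
  d0 <- dssim_statistic(s, s, "VIS", fg, obs$known, cfg)
  expect_equal(d0$statistic, 0, tolerance = 1e-12)
  est <- demosaic(obs, "bilinear_1d")
  d1 <- dssim_statistic(s, est, "VIS", fg, obs$known, cfg)
  expect_gte(d1$statistic, 0)
  expect_lte(d1$statistic, 1)
  expect_true(all(d1$map >= 0 & d1$map <= 1))
  # uniform pair: variances vanish and only the luminance term remains
  u_ref <- mosaicbench:::.as_scene(array(0.5, c(24, 24, 6)))
  u_est <- mosaicbench:::.as_scene(array(0.25, c(24, 24, 6)))
  fg_u <- compute_foreground_mask(u_ref, tau = 0.01)
  du <- dssim_statistic(u_ref, u_est, "VIS", fg_u, obs$known[1:24, 1:24, ],
                        cfg)
  c1 <- (0.01 * 1)^2
  closed <- (1 - (2 * 0.5 * 0.25 + c1) / (0.5^2 + 0.25^2 + c1)) / 2
  expect_equal(unique(round(as.vector(du$map), 10)), round(closed, 10))
  expect_equal(du$statistic, closed, tolerance = 1e-9)
})

test_that("the rgbir NIR group pools DSSIM over its single channel", {
  s <- generate_scene(small_params(seed = 6, h = 32, w = 32))
  fg <- compute_foreground_mask(s)
  obs <- apply_mosaic(s, build_mosaic_layout("rgbir"))
  est <- demosaic(obs, "bilinear_1d")
  d <- dssim_statistic(s, est, "NIR", fg, obs$known)
  expect_identical(d$channels, "NIR_1")
  expect_true(d$defined)
})

test_that("linear-RGB triplets convert to CIELAB correctly", {
  expect_equal(triplet_to_lab(c(1, 1, 1)), c(L = 100, a = 0, b = 0),
               tolerance = 1e-12)
  expect_equal(unname(triplet_to_lab(c(0, 0, 0))), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(unname(triplet_to_lab(c(0.5, 0.2, 0.2))),
               oracle_lab(c(0.5, 0.2, 0.2)), tolerance = 1e-6)
  set.seed(31)
  for (rep in 1:20) {
    rgb <- stats::runif(3)
    expect_equal(unname(triplet_to_lab(rgb)), oracle_lab(rgb),
                 tolerance = 1e-6)
  }
})

test_that("CIE76 equals 100 for black versus white and CIEDE2000 matches farver", {
  ref <- mosaicbench:::.as_scene(array(0, c(16, 16, 6)))
  est <- mosaicbench:::.as_scene(array(1, c(16, 16, 6)))
  fg <- structure(list(mask = matrix(TRUE, 16, 16), method = "fixed",
                       tau = 0), class = "foreground_mask")
  known <- layout_known_mask(build_mosaic_layout("bioinspired"), 16, 16)
  de <- delta_e_statistic(ref, est, "VIS", fg, known)
  expect_equal(unique(as.vector(de$map)), 100, tolerance = 1e-12)
  expect_equal(de$statistic, 100, tolerance = 1e-12)
  skip_if_not_installed("farver")
  set.seed(55)
  for (rep in 1:25) {
    lab1 <- matrix(c(stats::runif(1, 0, 100), stats::runif(2, -60, 60)), 1)
    lab2 <- matrix(c(stats::runif(1, 0, 100), stats::runif(2, -60, 60)), 1)
    got <- mosaicbench:::.ciede2000(lab1, lab2)
    ref_val <- as.numeric(farver::compare_colour(lab1, lab2,
                                                 from_space = "lab",
                                                 method = "cie2000"))
    expect_equal(got, ref_val, tolerance = 1e-6)
  }
})

test_that("delta-E statistics honor masks, the JND, and missing channels", {
  s <- generate_scene(small_params(seed = 13, h = 32, w = 32))
  fg <- compute_foreground_mask(s)
  obs <- apply_mosaic(s, build_mosaic_layout("bioinspired"))
  est <- demosaic(obs, "bilinear_1d")
  de <- delta_e_statistic(s, est, "VIS", fg, obs$known)
  expect_true(de$defined)
  expect_gte(de$statistic, 0)
  # perceptibility flags: strictly above the JND only
  expect_identical(de$perceptible, de$map > 1)
  expect_false(mosaicbench:::.perceptible(1.0, 1.0))
  expect_true(mosaicbench:::.perceptible(1.0 + 1e-12, 1.0))
  d0 <- delta_e_statistic(s, s, "VIS", fg, obs$known)
  expect_equal(d0$statistic, 0, tolerance = 1e-12)
  # rgbir cannot provide a NIR triplet: undefined, not an error
  obs_r <- apply_mosaic(s, build_mosaic_layout("rgbir"))
  est_r <- demosaic(obs_r, "bilinear_1d")
  de_r <- delta_e_statistic(s, est_r, "NIR", fg, obs_r$known)
  expect_false(de_r$defined)
  expect_true(is.na(de_r$statistic))
})

test_that("error statistics respond monotonically to error scaling", {
  s <- generate_scene(small_params(seed = 21, h = 32, w = 32))
  fg <- compute_foreground_mask(s)
  obs <- apply_mosaic(s, build_mosaic_layout("bioinspired"))
  est <- demosaic(obs, "bilinear_1d")
  # doubling the deviation from the reference never decreases SAE/MAE/dE
  est2 <- mosaicbench:::.as_scene(
    mosaicbench:::.clamp01(s + 2 * (est - s)))
  for (ch in c("VIS_R", "NIR_2")) {
    expect_gte(sum_absolute_error(s, est2, fg, ch),
               sum_absolute_error(s, est, fg, ch))
    expect_gte(mean_absolute_error(s, est2, fg, obs$known, ch),
               mean_absolute_error(s, est, fg, obs$known, ch))
  }
  # the 100th percentile upper-bounds the 99th
  cfg <- metric_config()
  cfg100 <- metric_config(percentile = 1)
  expect_gte(dssim_statistic(s, est, "VIS", fg, obs$known, cfg100)$statistic,
             dssim_statistic(s, est, "VIS", fg, obs$known, cfg)$statistic)
})
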