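# Synthetic scene generator: determinism, degenerate configurations,
# fixtures, noise model.

test_that("identical parameters produce bit-identical scenes", {
  p <- small_params(seed = 42)
  expect_identical(generate_scene(p), generate_scene(p))
  s1 <- generate_scene(small_params(seed = 1))
  s2 <- generate_scene(small_params(seed = 2))
  expect_false(identical(s1, s2))
})

test_that("scenes are finite and bounded in [0,1]", {
  for (sd in 1:5) {
    s <- generate_scene(small_params(seed = sd))
    expect_true(all(is.finite(s)))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("degenerate configuration yields flat VIS and zero NIR", {
  p <- synth_params(seed = 7, height = 32, width = 32,
                    n_vessels = 0, n_blobs = 0,
                    background_smoothness = Inf)
  s <- generate_scene(p)
  for (k in 1:3)
    expect_equal(as.vector(s[, , k]),
                 rep(p$vis_base_color[k], 32 * 32), tolerance = 1e-12)
  expect_equal(max(abs(s[, , 4:6])), 0)
})

test_that("VIS and NIR groups are uncorrelated across seeds", {
  # empirical check of the channel-independence construction at default
  # scene settings
  n_seeds <- 100
  cors <- numeric(0)
  for (sd in seq_len(n_seeds)) {
    s <- generate_scene(synth_params(seed = sd))
    for (i in 1:3) for (j in 4:6) {
      v <- as.vector(s[, , i]); u <- as.vector(s[, , j])
      if (stats::sd(v) > 0 && stats::sd(u) > 0)
        cors <- c(cors, stats::cor(v, u))
    }
  }
  expect_lt(mean(abs(cors)), 0.1)
})

test_that("invalid scene parameters are rejected", {
  expect_error(synth_params(height = 8), class = "param_error")
  expect_error(synth_params(vis_base_color = c(2, 0, 0)),
               class = "param_error")
  expect_error(synth_params(nir_crosstalk = matrix(1, 3, 3)),
               class = "param_error")
  expect_error(synth_params(blob_sigma_range = c(4, 2)),
               class = "param_error")
  expect_error(synth_params(noise_gain = -1), class = "param_error")
})

test_that("ramp fixtures evaluate the stated polynomials", {
  r0 <- generate_ramp_fixture(16, 16, "row", 0)
  expect_true(all(r0 == 0.5))
  r1 <- generate_ramp_fixture(16, 5, "column", 1)
  expect_equal(r1[3, , 1], c(0, 0.25, 0.5, 0.75, 1))
  r3 <- generate_ramp_fixture(20, 16, "row", 3)
  expect_equal(r3[, 4, 2], ((0:19) / 19)^3, tolerance = 1e-14)
  rd <- generate_ramp_fixture(10, 12, "diagonal", 1)
  expect_equal(unname(rd[3, 5, 6]), (2 + 4) / (9 + 11), tolerance = 1e-14)
  expect_error(generate_ramp_fixture(16, 16, "row", 2),
               class = "param_error")
})

test_that("point-pair fixture has the expected extrema and symmetry", {
  # internal extrema = sign changes of the (nonzero) first differences
  count_extrema <- function(prof) {
    d <- diff(prof)
    sum(diff(sign(d[d != 0])) != 0)
  }
  # resolved pair: two maxima and one minimum on the center-row profile
  s <- generate_point_pair(17, 33, separation = 8, sigma = 1)
  prof <- s[9, , 4]
  expect_equal(count_extrema(prof[prof > 1e-12]), 3)
  # coincident sources: a single maximum
  s0 <- generate_point_pair(17, 33, separation = 0, sigma = 2)
  prof0 <- s0[9, , 4]
  expect_equal(count_extrema(prof0), 1)
  # mirror symmetry about the vertical centerline
  expect_equal(s[, , 4], s[, rev(seq_len(33)), 4], tolerance = 1e-14)
  # other channels stay dark
  expect_equal(max(abs(s[, , -4])), 0)
  expect_error(generate_point_pair(17, 17, separation = 40, sigma = 1),
               class = "param_error")
})

test_that("sensor noise is seeded, optional, and follows the variance model", {
  s <- generate_scene(small_params(seed = 3))
  expect_identical(add_sensor_noise(s, 0, 0, seed = 1), s)
  n1 <- add_sensor_noise(s, 0.01, 0.002, seed = 5)
  n2 <- add_sensor_noise(s, 0.01, 0.002, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_sensor_noise(s, 0.01, 0.002, seed = 6)))
  # at constant x = 0.25 with gain 0.004 the model variance is 0.001
  flat <- mosaicbench:::.as_scene(array(0.25, c(132, 132, 6)))
  noisy <- add_sensor_noise(flat, 0.004, 0, seed = 11)
  emp_sd <- stats::sd(noisy[, , 1:6] - 0.25)
  expect_lt(abs(emp_sd - sqrt(0.001)) / sqrt(0.001), 0.05)
})
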