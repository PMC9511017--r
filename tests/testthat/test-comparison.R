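# Quantile curves, percent-change curves, and routine ranking.

test_that("quantile functions follow order-statistic interpolation", {
  flat <- quantile_function(rep(0.3, 50), grid = c(0.1, 0.5, 0.9))
  expect_equal(flat$value, rep(0.3, 3))
  q <- quantile_function(c(1, 2, 3, 4), grid = 0.5)
  expect_equal(q$value, 2.5)
  set.seed(17)
  curve <- quantile_function(stats::rexp(500))
  expect_true(all(diff(curve$value) >= 0))
  expect_error(quantile_function(numeric(0)), class = "degenerate_error")
  expect_error(quantile_function(1:5, grid = c(0, 0.5)),
               class = "param_error")
})

test_that("percent-change curves compare matched quantile grids", {
  g <- c(0.25, 0.5, 0.75)
  base <- quantile_function(c(2, 2, 2, 2), grid = g, metric = "DE_VIS")
  alt <- quantile_function(c(1, 1, 1, 1), grid = g, metric = "DE_VIS")
  pc <- percent_change_curve(base, alt)
  expect_equal(pc$percent_change, rep(-50, 3))
  same <- percent_change_curve(base, base)
  expect_equal(same$percent_change, rep(0, 3))
  zero_base <- quantile_function(c(0, 0, 3, 4), grid = g, metric = "DE_VIS")
  pc0 <- percent_change_curve(zero_base, alt)
  expect_true(is.na(pc0$percent_change[1]))
  expect_false(anyNA(pc0$percent_change[pc0$quantile > 0.5]))
  other_grid <- quantile_function(c(1, 2), grid = c(0.4, 0.8),
                                  metric = "DE_VIS")
  expect_error(percent_change_curve(base, other_grid),
               class = "param_error")
  other_metric <- quantile_function(c(1, 2, 3), grid = g,
                                    metric = "DSSIM_VIS")
  expect_error(percent_change_curve(base, other_metric),
               class = "param_error")
})

make_perceptual_table <- function(sensor, de_vis, dssim_vis, de_nir,
                                  dssim_nir) {
  routines <- demosaic_routines()
  do.call(rbind, lapply(seq_along(routines), function(i) {
    metric_table_row(sensor, routines[i],
                     sae = stats::setNames(rep(NA_real_, 6),
                                           scene_channels()),
                     mae = stats::setNames(rep(NA_real_, 6),
                                           scene_channels()),
                     dssim_vis = dssim_vis[i], de_vis = de_vis[i],
                     dssim_nir = dssim_nir[i], de_nir = de_nir[i])
  }))
}

test_that("ranking is order-invariant, shift-invariant, and handles ties", {
  tb <- make_perceptual_table("bioinspired",
                              de_vis = c(3, 1, 2, 5, 4),
                              dssim_vis = c(0.2, 0.1, 0.3, 0.5, 0.4),
                              de_nir = c(1, 2, 3, 4, 5),
                              dssim_nir = c(0.01, 0.02, 0.03, 0.04, 0.05))
  r1 <- rank_routines(tb, "bioinspired")
  r2 <- rank_routines(tb[sample.int(5), ], "bioinspired")
  expect_equal(r1$average_rank, r2$average_rank)
  expect_equal(r1$ordering, r2$ordering)
  # adding a constant to one metric leaves its ranks unchanged
  tb_shift <- tb
  tb_shift$DE_VIS <- tb_shift$DE_VIS + 7
  expect_equal(rank_routines(tb_shift, "bioinspired")$ranks[, "DE_VIS"],
               r1$ranks[, "DE_VIS"])
  # a full tie puts every routine at the middle rank
  tb_tie <- make_perceptual_table("bioinspired", rep(1, 5), rep(1, 5),
                                  rep(1, 5), rep(1, 5))
  expect_equal(unname(rank_routines(tb_tie, "bioinspired")$average_rank),
               rep(3, 5))
  # average rank stays within [1, 5] and per-metric ranks sum to 15
  expect_true(all(r1$average_rank >= 1 & r1$average_rank <= 5))
  expect_true(all(colSums(r1$ranks) == 15))
  expect_error(rank_routines(tb[-1, ], "bioinspired"),
               class = "param_error")
  expect_error(rank_routines(tb, "rgbir"), class = "param_error")
})

test_that("pooled SAE/MAE ranks combine channels as sums and means", {
  routines <- demosaic_routines()
  tb <- do.call(rbind, lapply(seq_along(routines), function(i) {
    sae <- stats::setNames(c(i, i, i, 6 - i, NA, NA), scene_channels())
    mae <- stats::setNames(c(i, i, i, 6 - i, NA, NA), scene_channels()) / 10
    metric_table_row("rgbir", routines[i], sae, mae,
                     dssim_vis = NA, de_vis = NA,
                     dssim_nir = NA, de_nir = NA)
  }))
  rs <- rank_routines(tb, "rgbir", mode = "pooled_sae")
  expect_equal(unname(rs$ranks[, "SAE_VIS_pooled"]), 1:5)
  expect_equal(unname(rs$ranks[, "SAE_NIR_pooled"]), 5:1)
  rm_ <- rank_routines(tb, "rgbir", mode = "pooled_mae")
  expect_equal(unname(rm_$ranks[, "MAE_VIS_pooled"]), 1:5)
})
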