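# End-to-end pipeline driver: scene -> mosaic -> demosaic -> metrics ->
# quantile curves and rankings, as a pure composition of the other modules.

#' Pipeline run configuration
#'
#' @param synth [synth_params()] describing the synthetic scene (its seed is
#'   overridden by `seed`); ignored when `scene` is given.
#' @param scene Optional user-supplied six-channel `scene_image` used as the
#'   unmosaiced ground truth (no noise is added to it).
#' @param sensors Character vector from `c("rgbir", "bioinspired")`.
#' @param routines Character vector from [demosaic_routines()].
#' @param metric_cfg A [metric_config()].
#' @param foreground List with `method` (`"fixed"` or `"otsu"`) and `tau`.
#' @param bioinspired_variant `"checkerboard"` or `"column_stripes"`.
#' @param percent_change_pairs Named list, per sensor, of `c(base, alt)`
#'   routine pairs for percent-change curves.  Defaults to the baseline
#'   bilinear routine against the best cubic-polynomial routine for each
#'   sensor (1-D for RGB-IR, 2-D for bioinspired).
#' @param seed Integer seed controlling scene synthesis and sensor noise.
#' @param outdir Optional directory; when given, all outputs are written
#'   there (TIFF + sidecars, CSV tables and curves, JSON reports).
#' @return A `run_config` object.
#' @export
run_config <- function(synth = synth_params(),
                       scene = NULL,
                       sensors = c("rgbir", "bioinspired"),
                       routines = demosaic_routines(),
                       metric_cfg = metric_config(),
                       foreground = list(method = "fixed", tau = 0.02),
                       bioinspired_variant = "checkerboard",
                       percent_change_pairs = list(
                         rgbir = c("bilinear_1d", "cubic_poly_1d"),
                         bioinspired = c("bilinear_1d", "cubic_poly_2d")),
                       seed = 1L,
                       outdir = NULL) {
  if (length(sensors) == 0L ||
      !all(sensors %in% c("rgbir", "bioinspired")))
    .stopf("param_error", "'sensors' must be a non-empty subset of rgbir/bioinspired")
  if (length(routines) == 0L || !all(routines %in% demosaic_routines()))
    .stopf("param_error", "'routines' must be a non-empty subset of %s",
           paste(demosaic_routines(), collapse = ", "))
  if (!inherits(synth, "synth_params"))
    .stopf("param_error", "'synth' must come from synth_params()")
  if (!is.null(scene)) .check_scene(scene)
  if (!inherits(metric_cfg, "metric_config"))
    .stopf("param_error", "'metric_cfg' must come from metric_config()")
  .check_number(seed, "seed", integer = TRUE)
  structure(list(synth = synth, scene = scene,
                 sensors = unique(sensors), routines = unique(routines),
                 metric_cfg = metric_cfg, foreground = foreground,
                 bioinspired_variant = bioinspired_variant,
                 percent_change_pairs = percent_change_pairs,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[mosaicbench] %s (%.2fs elapsed)",
                               sprintf(fmt, ...),
                               proc.time()[["elapsed"]]))
}

.perceptual_metric_names <- c("DE_VIS", "DSSIM_VIS", "DE_NIR", "DSSIM_NIR")

#' Run the full evaluation pipeline
#'
#' For every configured (sensor, routine) pair: sample the ground-truth
#' scene through the sensor's mosaic, demosaic it, and score the
#' reconstruction.  Emits the full metric table (per-channel SAE/MAE plus
#' 99th-percentile DSSIM and color difference per spectral group), quantile
#' curves for the four perceptual metrics, percent-change curves between the
#' configured routine pairs, and rank reports (perceptual, pooled SAE,
#' pooled MAE) per sensor.  Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @param verbose Log stage-level progress via `message()`.
#' @return An `evaluation_result` list: `metric_table`, `quantile_curves`
#'   (per sensor / routine / metric), `percent_change` (per sensor),
#'   `rank_reports` (per sensor / mode), `foreground`, `config`, `seed`.
#' @export
run_evaluation <- function(config = run_config(), verbose = FALSE) {
  if (!inherits(config, "run_config"))
    .stopf("param_error", "'config' must come from run_config()")
  cfg <- config$metric_cfg
  if (is.null(config$scene)) {
    synth <- config$synth
    synth$seed <- config$seed
    truth <- generate_scene(synth)
    truth <- add_sensor_noise(truth, synth$noise_gain,
                              synth$read_noise_sigma,
                              seed = (config$seed + 77) %% 2147483647)
    .stage_log(verbose, "scene: synthesized %dx%d (seed %d)",
               synth$height, synth$width, config$seed)
  } else {
    truth <- .as_scene(config$scene)
    .stage_log(verbose, "scene: user-supplied %dx%d",
               dim(truth)[1], dim(truth)[2])
  }
  fg <- compute_foreground_mask(truth,
                                method = config$foreground$method,
                                tau = if (is.null(config$foreground$tau))
                                  0.02 else config$foreground$tau)
  .stage_log(verbose, "foreground: %d/%d pixels (tau %.4g)",
             sum(fg$mask), length(fg$mask), fg$tau)
  rows <- list()
  curves <- list()
  reports <- list()
  pchange <- list()
  for (sensor in config$sensors) {
    layout <- if (sensor == "bioinspired")
      build_mosaic_layout("bioinspired", config$bioinspired_variant)
    else build_mosaic_layout("rgbir")
    obs <- apply_mosaic(truth, layout)
    .stage_log(verbose, "mosaic: %s", sensor)
    curves[[sensor]] <- list()
    for (routine in config$routines) {
      est <- demosaic(obs, demosaic_spec(routine))
      .stage_log(verbose, "demosaic: %s / %s", sensor, routine)
      sae <- vapply(.CHANNELS, function(ch)
        sum_absolute_error(truth, est, fg, ch), numeric(1))
      mae <- vapply(.CHANNELS, function(ch) {
        if (all(is.na(est[, , ch]))) NA_real_
        else mean_absolute_error(truth, est, fg, obs$known, ch)
      }, numeric(1))
      ds_vis <- dssim_statistic(truth, est, "VIS", fg, obs$known, cfg)
      ds_nir <- dssim_statistic(truth, est, "NIR", fg, obs$known, cfg)
      de_vis <- delta_e_statistic(truth, est, "VIS", fg, obs$known, cfg)
      de_nir <- delta_e_statistic(truth, est, "NIR", fg, obs$known, cfg)
      rows[[length(rows) + 1L]] <- metric_table_row(
        sensor, routine, sae, mae,
        dssim_vis = ds_vis$statistic, de_vis = de_vis$statistic,
        dssim_nir = ds_nir$statistic, de_nir = de_nir$statistic)
      stats_list <- list(DE_VIS = de_vis, DSSIM_VIS = ds_vis,
                         DE_NIR = de_nir, DSSIM_NIR = ds_nir)
      curves[[sensor]][[routine]] <- lapply(
        .perceptual_metric_names, function(mn) {
          st <- stats_list[[mn]]
          if (!isTRUE(st$defined)) return(NULL)
          grp <- if (grepl("VIS$", mn)) "VIS" else "NIR"
          idx <- .channel_index(channel_group(grp))
          idx <- idx[vapply(idx, function(i) !all(is.na(est[, , i])),
                            logical(1))]
          sel <- fg$mask & .group_unknown_any(obs$known, idx)
          quantile_function(st$map[sel], metric = mn, sensor = sensor,
                            routine = routine)
        })
      names(curves[[sensor]][[routine]]) <- .perceptual_metric_names
      .stage_log(verbose, "metrics: %s / %s", sensor, routine)
    }
    pair <- config$percent_change_pairs[[sensor]]
    if (!is.null(pair) && all(pair %in% config$routines)) {
      pchange[[sensor]] <- lapply(.perceptual_metric_names, function(mn) {
        base <- curves[[sensor]][[pair[1]]][[mn]]
        alt <- curves[[sensor]][[pair[2]]][[mn]]
        if (is.null(base) || is.null(alt)) return(NULL)
        percent_change_curve(base, alt)
      })
      names(pchange[[sensor]]) <- .perceptual_metric_names
    }
  }
  metric_table <- do.call(rbind, rows)
  if (all(demosaic_routines() %in% config$routines)) {
    for (sensor in config$sensors)
      reports[[sensor]] <- list(
        perceptual = rank_routines(metric_table, sensor, "perceptual"),
        pooled_sae = rank_routines(metric_table, sensor, "pooled_sae"),
        pooled_mae = rank_routines(metric_table, sensor, "pooled_mae"))
  }
  result <- structure(list(metric_table = metric_table,
                           quantile_curves = curves,
                           percent_change = pchange,
                           rank_reports = reports,
                           foreground = fg,
                           config = config,
                           seed = config$seed),
                      class = "evaluation_result")
  if (!is.null(config$outdir)) .write_evaluation(result, truth, verbose)
  result
}

.write_evaluation <- function(result, truth, verbose = FALSE) {
  outdir <- result$config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_min <- result$config[c("sensors", "routines", "seed",
                             "bioinspired_variant")]
  write_multichannel(truth, file.path(outdir, "unmosaiced.tiff"),
                     params = cfg_min, seed = result$seed)
  write_metric_table(result$metric_table,
                     file.path(outdir, "metric_table.csv"))
  for (sensor in names(result$quantile_curves))
    for (routine in names(result$quantile_curves[[sensor]]))
      for (mn in names(result$quantile_curves[[sensor]][[routine]])) {
        cv <- result$quantile_curves[[sensor]][[routine]][[mn]]
        if (is.null(cv)) next
        write_curve(cv, file.path(outdir, sprintf("quantile_%s_%s_%s.csv",
                                                  sensor, routine, mn)))
      }
  for (sensor in names(result$percent_change))
    for (mn in names(result$percent_change[[sensor]])) {
      cv <- result$percent_change[[sensor]][[mn]]
      if (is.null(cv)) next
      write_curve(cv, file.path(outdir, sprintf("percent_change_%s_%s.csv",
                                                sensor, mn)))
    }
  for (sensor in names(result$rank_reports))
    for (mode in names(result$rank_reports[[sensor]]))
      write_rank_report(result$rank_reports[[sensor]][[mode]],
                        file.path(outdir, sprintf("ranks_%s_%s.json",
                                                  sensor, mode)))
  .stage_log(verbose, "wrote outputs to %s", outdir)
  invisible(outdir)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %d metric rows, sensors: %s\n",
              nrow(x$metric_table),
              paste(unique(x$metric_table$sensor), collapse = ", ")))
  print(x$metric_table[, c("sensor", "routine", "DSSIM_VIS", "DE_VIS",
                           "DSSIM_NIR", "DE_NIR")], digits = 4)
  invisible(x)
}
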