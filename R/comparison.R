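# Comparison of sensors and demosaicing routines: empirical quantile
# functions of per-pixel metric maps, percent-change curves between routines,
# and per-metric / average rankings.

#' Default quantile grid
#'
#' 999 points from 0.001 to 0.999 plus 0.9999 to expose tail behavior.
#'
#' @return Numeric vector of quantile fractions.
#' @export
default_quantile_grid <- function() c(seq(0.001, 0.999, by = 0.001), 0.9999)

#' Empirical quantile function of a metric map
#'
#' Linear interpolation between order statistics (the common default
#' convention, `stats::quantile` type 7), evaluated on a grid of fractions.
#' Each point of the curve states the metric value not exceeded by that
#' fraction of pixels.
#'
#' @param values Numeric per-pixel metric samples (`NA`s dropped).
#' @param grid Quantile fractions in `(0, 1]`.
#' @param metric,sensor,routine Optional identifiers stored as attributes.
#' @return A `quantile_curve`: data frame with columns `quantile`, `value`.
#' @export
quantile_function <- function(values, grid = default_quantile_grid(),
                              metric = NULL, sensor = NULL, routine = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    .stopf("degenerate_error", "no samples to build a quantile function from")
  if (!is.numeric(grid) || length(grid) == 0L ||
      any(grid <= 0) || any(grid > 1))
    .stopf("param_error", "'grid' fractions must lie in (0, 1]")
  out <- data.frame(quantile = grid,
                    value = as.numeric(stats::quantile(values, grid,
                                                       type = 7,
                                                       names = FALSE)))
  attr(out, "metric") <- metric
  attr(out, "sensor") <- sensor
  attr(out, "routine") <- routine
  class(out) <- c("quantile_curve", "data.frame")
  out
}

#' Percent change between two quantile curves
#'
#' At each quantile `q`, `100 * (alt(q) - base(q)) / base(q)`; where the base
#' curve is zero the change is undefined and reported as `NA`.
#'
#' @param base,alt `quantile_curve`s on identical grids and for the same
#'   metric.
#' @return A `percent_change_curve`: data frame with columns `quantile`,
#'   `percent_change`.
#' @export
percent_change_curve <- function(base, alt) {
  if (!inherits(base, "quantile_curve") || !inherits(alt, "quantile_curve"))
    .stopf("param_error", "'base' and 'alt' must be quantile curves")
  if (length(base$quantile) != length(alt$quantile) ||
      any(abs(base$quantile - alt$quantile) > 1e-12))
    .stopf("param_error", "quantile grids do not match")
  mb <- attr(base, "metric"); ma <- attr(alt, "metric")
  if (!is.null(mb) && !is.null(ma) && !identical(mb, ma))
    .stopf("param_error", "curves describe different metrics (%s vs %s)",
           mb, ma)
  pc <- 100 * (alt$value - base$value) / base$value
  pc[base$value == 0] <- NA_real_
  out <- data.frame(quantile = base$quantile, percent_change = pc)
  attr(out, "metric") <- mb
  class(out) <- c("percent_change_curve", "data.frame")
  out
}

.metric_columns <- function() {
  c(paste0("SAE_", .CHANNELS), paste0("MAE_", .CHANNELS),
    "DSSIM_VIS", "DE_VIS", "DSSIM_NIR", "DE_NIR")
}

#' Assemble a metric table row
#'
#' @param sensor,routine Identifiers.
#' @param sae,mae Named numeric vectors over [scene_channels()] (`NA` for
#'   channels the sensor cannot provide).
#' @param dssim_vis,de_vis,dssim_nir,de_nir Group statistics (`NA` when
#'   undefined).
#' @return One-row data frame with the standard metric-table columns.
#' @export
metric_table_row <- function(sensor, routine, sae, mae,
                             dssim_vis, de_vis, dssim_nir, de_nir) {
  row <- data.frame(sensor = sensor, routine = routine,
                    stringsAsFactors = FALSE)
  for (ch in .CHANNELS) row[[paste0("SAE_", ch)]] <- unname(sae[ch])
  for (ch in .CHANNELS) row[[paste0("MAE_", ch)]] <- unname(mae[ch])
  row$DSSIM_VIS <- dssim_vis; row$DE_VIS <- de_vis
  row$DSSIM_NIR <- dssim_nir; row$DE_NIR <- de_nir
  row
}

.require_routines <- function(tb) {
  if (!all(demosaic_routines() %in% tb$routine))
    .stopf("param_error", "the table must contain all five routines: %s",
           paste(setdiff(demosaic_routines(), tb$routine), collapse = ", "))
  tb[match(demosaic_routines(), tb$routine), , drop = FALSE]
}

.pooled_group <- function(tb, prefix, group, combine) {
  cols <- paste0(prefix, "_", channel_group(group))
  have <- cols[vapply(cols, function(cc) !all(is.na(tb[[cc]])), logical(1))]
  if (length(have) == 0L)
    .stopf("param_error", "no %s %s columns available", group, prefix)
  if (any(vapply(have, function(cc) anyNA(tb[[cc]]), logical(1))))
    .stopf("param_error", "metric column with partial values: %s group", group)
  m <- as.matrix(tb[, have, drop = FALSE])
  apply(m, 1L, combine)
}

#' Rank demosaicing routines from a metric table
#'
#' Smaller metric values are better.  Within each metric, routines receive
#' ranks 1..5 with ties assigned the average of the tied positions; the
#' average rank is the mean of the per-metric ranks and the ordering sorts
#' routines from best (smallest average rank) to worst.
#'
#' Modes:
#' * `"perceptual"`: ranks over the available perceptual metrics — `DE_VIS`,
#'   `DSSIM_VIS`, `DE_NIR`, `DSSIM_NIR` for a sensor with three NIR channels;
#'   `DE_NIR` is dropped when unavailable (RGB-IR).
#' * `"pooled_sae"`: ranks on the summed per-channel SAE of the pooled VIS
#'   and pooled NIR channels.
#' * `"pooled_mae"`: ranks on the mean per-channel MAE of the pooled VIS and
#'   pooled NIR channels.
#'
#' @param table A metric table (rows from [metric_table_row()], e.g. built by
#'   [run_evaluation()] or typed in from published results).
#' @param sensor `"rgbir"` or `"bioinspired"`: the sensor whose rows to rank.
#' @param mode `"perceptual"`, `"pooled_sae"`, or `"pooled_mae"`.
#' @return A `rank_report`: list with `metrics` (values matrix), `ranks`,
#'   `average_rank` (named, best = smallest), and `ordering` (routine names
#'   best to worst).
#' @export
rank_routines <- function(table, sensor,
                          mode = c("perceptual", "pooled_sae",
                                   "pooled_mae")) {
  mode <- match.arg(mode)
  if (!is.data.frame(table) ||
      !all(c("sensor", "routine") %in% names(table)))
    .stopf("param_error",
           "'table' must be a data frame with sensor and routine columns")
  tb <- table[table$sensor == sensor, , drop = FALSE]
  if (nrow(tb) == 0L)
    .stopf("param_error", "no rows for sensor '%s'", sensor)
  tb <- .require_routines(tb)
  metmat <- switch(mode,
    perceptual = {
      cand <- c("DE_VIS", "DSSIM_VIS", "DE_NIR", "DSSIM_NIR")
      missing <- setdiff(cand, names(tb))
      if (length(missing) > 0L)
        .stopf("param_error", "missing metric columns: %s",
               paste(missing, collapse = ", "))
      keep <- cand[vapply(cand, function(cc) !all(is.na(tb[[cc]])),
                          logical(1))]
      if (any(vapply(keep, function(cc) anyNA(tb[[cc]]), logical(1))))
        .stopf("param_error", "perceptual metric defined for only some routines")
      as.matrix(tb[, keep, drop = FALSE])
    },
    pooled_sae = cbind(SAE_VIS_pooled = .pooled_group(tb, "SAE", "VIS", sum),
                       SAE_NIR_pooled = .pooled_group(tb, "SAE", "NIR", sum)),
    pooled_mae = cbind(MAE_VIS_pooled = .pooled_group(tb, "MAE", "VIS", mean),
                       MAE_NIR_pooled = .pooled_group(tb, "MAE", "NIR", mean)))
  rownames(metmat) <- tb$routine
  ranks <- apply(metmat, 2L, rank, ties.method = "average")
  rownames(ranks) <- tb$routine
  avg <- rowMeans(ranks)
  structure(list(sensor = sensor, mode = mode,
                 metrics = metmat, ranks = ranks,
                 average_rank = avg,
                 ordering = names(sort(avg))),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("<rank_report> sensor %s, mode %s\n", x$sensor, x$mode))
  cat("  average rank (best first):\n")
  avg <- sort(x$average_rank)
  for (i in seq_along(avg))
    cat(sprintf("   %d. %-16s %.3f\n", i, names(avg)[i], avg[i]))
  invisible(x)
}
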