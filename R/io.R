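# File formats: multi-page float TIFF with JSON sidecars for images and
# observations, CSV for metric tables and curves, JSON for rank reports.

.sidecar_path <- function(path) paste0(path, ".json")

.provenance <- function(seed = NULL, config = NULL) {
  prov <- list(package = "mosaicbench",
               version = as.character(utils::packageVersion("mosaicbench")))
  if (!is.null(seed)) prov$seed <- seed
  if (!is.null(config)) prov$config_hash <- .config_hash(config)
  prov
}

# md5 of the canonical JSON rendering of an object (used as the config hash)
.config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write a six-channel image as multi-page float TIFF
#'
#' One 32-bit-float page per channel in canonical order, with a JSON sidecar
#' (`<path>.json`) recording channel labels, generation parameters, and
#' provenance (package version, seed, config hash).
#'
#' @param image A six-channel `scene_image` with values in `[0,1]`.
#' @param path Output TIFF path.
#' @param params Optional parameter list (e.g. [synth_params()]) stored in
#'   the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_multichannel <- function(image, path, params = NULL, seed = NULL) {
  .check_scene(image, "image")
  pages <- lapply(seq_len(6L), function(i) {
    p <- image[, , i]
    p[is.na(p)] <- 0
    .clamp01(p)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(channels = as.list(.CHANNELS),
               height = dim(image)[1], width = dim(image)[2],
               params = params,
               provenance = .provenance(seed = seed, config = params))
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(path)
}

#' Read a six-channel image from multi-page TIFF
#'
#' Expects six grayscale pages in canonical channel order plus the JSON
#' sidecar written by [write_multichannel()].  Integer TIFFs are linearly
#' scaled to `[0,1]` by their bit-depth maximum (the `tiff` package's
#' normalization), so 16-bit inputs are divided by 65535.
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return A `scene_image`.
#' @export
read_multichannel <- function(path) {
  if (!file.exists(path))
    .stopf("format_error", "no such file: %s", path)
  side_path <- .sidecar_path(path)
  if (!file.exists(side_path))
    .stopf("format_error", "missing JSON sidecar: %s", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 6L)
    .stopf("format_error", "expected 6 pages, found %d", length(pages))
  if (any(!vapply(pages, is.matrix, logical(1))))
    .stopf("format_error", "pages must be single-sample (grayscale) images")
  labels <- unlist(side$channels)
  if (length(labels) != 6L || !identical(labels, .CHANNELS))
    .stopf("format_error", "sidecar channel labels do not match %s",
           paste(.CHANNELS, collapse = ", "))
  d <- dim(pages[[1]])
  scene <- array(0, c(d, 6L))
  for (i in seq_len(6L)) {
    if (!all(dim(pages[[i]]) == d))
      .stopf("format_error", "pages differ in size")
    scene[, , i] <- pages[[i]]
  }
  .as_scene(scene)
}

# run-length encode a logical vector (for mask sidecars)
.rle_encode <- function(x) {
  r <- rle(as.logical(x))
  list(first = r$values[1], lengths = as.integer(r$lengths))
}

.rle_decode <- function(enc, n) {
  vals <- rep(c(enc$first, !enc$first),
              length.out = length(enc$lengths))
  out <- rep(vals, enc$lengths)
  if (length(out) != n)
    .stopf("format_error", "mask run-length encoding does not match size")
  out
}

#' Write a mosaic observation
#'
#' Values as multi-page float TIFF (unknown entries stored as 0; the mask is
#' authoritative) plus a JSON sidecar with the run-length-encoded known mask
#' and the layout descriptor.
#'
#' @param obs A `mosaic_observation`.
#' @param path Output TIFF path.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_mosaic_observation <- function(obs, path, seed = NULL) {
  if (!inherits(obs, "mosaic_observation"))
    .stopf("param_error", "'obs' must come from apply_mosaic()")
  pages <- lapply(seq_len(6L), function(i) {
    p <- obs$values[, , i]
    p[is.na(p)] <- 0
    .clamp01(p)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(channels = as.list(.CHANNELS),
               height = dim(obs$values)[1], width = dim(obs$values)[2],
               layout = list(architecture = obs$layout$architecture,
                             variant = obs$layout$variant,
                             phase = obs$layout$phase),
               known_rle = lapply(seq_len(6L), function(i)
                 .rle_encode(obs$known[, , i])),
               provenance = .provenance(seed = seed))
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(path)
}

#' Read a mosaic observation written by [write_mosaic_observation()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return A `mosaic_observation`.
#' @export
read_mosaic_observation <- function(path) {
  side_path <- .sidecar_path(path)
  if (!file.exists(path) || !file.exists(side_path))
    .stopf("format_error", "missing observation file or sidecar for %s", path)
  side <- jsonlite::read_json(side_path, simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 6L)
    .stopf("format_error", "expected 6 pages, found %d", length(pages))
  h <- as.integer(side$height); w <- as.integer(side$width)
  values <- array(NA_real_, c(h, w, 6L),
                  dimnames = list(NULL, NULL, .CHANNELS))
  known <- array(FALSE, c(h, w, 6L), dimnames = list(NULL, NULL, .CHANNELS))
  for (i in seq_len(6L)) {
    enc <- side$known_rle[[i]]
    km <- matrix(.rle_decode(list(first = as.logical(enc$first),
                                  lengths = unlist(enc$lengths)), h * w),
                 h, w)
    known[, , i] <- km
    v <- pages[[i]]
    v[!km] <- NA_real_
    values[, , i] <- v
  }
  layout <- build_mosaic_layout(side$layout$architecture,
                                variant = if (!is.null(side$layout$variant))
                                  side$layout$variant,
                                phase = unlist(side$layout$phase))
  structure(list(values = values, known = known, layout = layout),
            class = "mosaic_observation")
}

.format_cell <- function(x) {
  if (is.na(x)) "—"
  else format(x, digits = 17, scientific = TRUE)
}

#' Write a metric table as CSV
#'
#' One row per (sensor, routine); numbers at full double precision in
#' scientific notation; statistics a sensor cannot provide are written as an
#' em-dash.
#'
#' @param table Metric table data frame ([run_evaluation()] output).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  out <- table
  for (nm in setdiff(names(out), c("sensor", "routine")))
    out[[nm]] <- vapply(out[[nm]], .format_cell, character(1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a metric table CSV written by [write_metric_table()]
#'
#' @param path CSV path.
#' @return Metric table data frame with `NA` for dashes.
#' @export
read_metric_table <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  for (nm in setdiff(names(tb), c("sensor", "routine"))) {
    v <- tb[[nm]]
    v[v == "—"] <- NA
    tb[[nm]] <- as.numeric(v)
  }
  tb
}

#' Write a quantile or percent-change curve as CSV
#'
#' @param curve A `quantile_curve` or `percent_change_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a rank report as JSON
#'
#' @param report A `rank_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rank_report <- function(report, path) {
  if (!inherits(report, "rank_report"))
    .stopf("param_error", "'report' must come from rank_routines()")
  payload <- list(sensor = report$sensor, mode = report$mode,
                  metrics = apply(report$metrics, 2L, as.list),
                  ranks = apply(report$ranks, 2L, as.list),
                  average_rank = as.list(report$average_rank),
                  ordering = report$ordering,
                  provenance = .provenance())
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
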