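# Disk formats: multi-page 32-bit float TIFF per channel (intensities mapped
# to [0, 1] with an affine transform recorded in the JSON sidecar), JSON for
# metadata and run reports, CSV for traces, line scans, and count tables.

#' Write a stack as a multi-page 32-bit TIFF
#'
#' Intensities are affinely mapped to `[0, 1]` for storage; the mapping is
#' returned and must be kept (the sidecar writers record it). Missing pixels
#' are stored as 0.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param path output file.
#' @return invisibly, list `offset`, `scale` with
#'   `stored = (value - offset) / scale`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  rng <- range(stack, finite = TRUE)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(i) {
    m <- (stack[, , i] - offset) / scale
    m[!is.finite(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(list(offset = offset, scale = scale))
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @param offset,scale affine mapping recorded at write time; the returned
#'   values are `stored * scale + offset`.
#' @return 3-D numeric array `[row, col, frame]`.
#' @export
read_stack_tiff <- function(path, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(NA_real_, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- p * scale + offset
  }
  arr
}

#' Write a two-channel time-lapse to disk
#'
#' One TIFF per channel plus a JSON sidecar with the acquisition metadata and
#' the intensity mappings.
#'
#' @param tl a [timelapse()].
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
write_timelapse <- function(tl, dir) {
  stopifnot(inherits(tl, "timelapse"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map_r <- write_stack_tiff(tl$reporter, file.path(dir, "reporter.tif"))
  map_a <- write_stack_tiff(tl$actin, file.path(dir, "actin.tif"))
  meta <- tl$meta
  sidecar <- list(
    pixel_size_um = meta$pixel_size_um,
    frame_interval_s = meta$frame_interval_s,
    ablation_frame = meta$ablation_frame,
    ablation_roi = apply(meta$ablation_roi, 1, as.numeric, simplify = FALSE),
    crop_size = meta$crop_size,
    channel_offset_s = meta$channel_offset_s,
    seed = meta$seed,
    reporter_intensity_map = map_r,
    actin_intensity_map = map_a
  )
  path <- file.path(dir, "meta.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a two-channel time-lapse written by [write_timelapse()]
#'
#' @param dir directory containing `reporter.tif`, `actin.tif`, `meta.json`.
#' @return a [timelapse()] (float32 storage precision).
#' @export
read_timelapse <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rmap <- meta$reporter_intensity_map
  amap <- meta$actin_intensity_map
  reporter <- read_stack_tiff(file.path(dir, "reporter.tif"),
                              rmap$offset, rmap$scale)
  actin <- read_stack_tiff(file.path(dir, "actin.tif"),
                           amap$offset, amap$scale)
  roi <- if (is.matrix(meta$ablation_roi)) {
    meta$ablation_roi
  } else {
    do.call(rbind, lapply(meta$ablation_roi, as.numeric))
  }
  timelapse(
    reporter = reporter, actin = actin,
    pixel_size_um = meta$pixel_size_um,
    frame_interval_s = meta$frame_interval_s,
    ablation_frame = meta$ablation_frame,
    ablation_roi = roi,
    crop_size = meta$crop_size,
    channel_offset_s = meta$channel_offset_s,
    seed = meta$seed
  )
}

#' Write a spatial probability map (32-bit TIFF + JSON geometry)
#'
#' @param map a [spatial_probability()] result.
#' @param path_tif,path_json output paths.
#' @export
write_probability_map <- function(map, path_tif, path_json) {
  stopifnot(inherits(map, "spatial_probability_map"))
  tiff::writeTIFF(map$prob, path_tif, bits.per.sample = 32L)
  geom <- list(
    n_timepoints = map$n_timepoints,
    strain_radius_um = map$strain_radius_um,
    pixel_size_um = map$pixel_size_um,
    ablation_segment = if (is.null(map$ablation_segment)) NULL else
      apply(map$ablation_segment, 1, as.numeric, simplify = FALSE)
  )
  jsonlite::write_json(geom, path_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path_tif)
}

#' Write a data frame as CSV (deterministic, full precision)
#'
#' @param df data frame.
#' @param path output file.
#' @export
write_csv_out <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a line-scan CSV
#'
#' Expected columns: `position_um`, `phalloidin`, `reporter`, and optionally
#' `organ_id`, `cell_id`. A file may hold several scans stacked row-wise, one
#' per `organ_id` x `cell_id` group; each group is validated separately.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_linescan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("organ_id", "cell_id") %in% names(df))) {
    groups <- split(df, list(df$organ_id, df$cell_id), drop = TRUE)
    lapply(groups, validate_linescan)
  } else {
    validate_linescan(df)
  }
  df
}

#' Read a count-table CSV
#'
#' Expected columns: `organ_id`, `image_id`, `cells_total`,
#' `cells_with_gaps`, `cells_dead`, `stereocilia_total`.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_count_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_count_table(df)
  df
}
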