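#' Crop window centred on the ablation region
#'
#' @param center_xy numeric `c(x, y)` centre in pixel coordinates (the
#'   ablation-segment midpoint, rounded to the nearest pixel).
#' @param size window side in pixels; must be odd so the centre pixel is
#'   unique (even requests are rejected, not adjusted).
#' @param pixel_size_um pixel size, um/pixel.
#' @return list of class `crop_window`.
#' @export
crop_window <- function(center_xy, size = 121L, pixel_size_um = 0.173) {
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("crop_window: size must be odd")
  stopifnot(length(center_xy) == 2, size >= 3)
  structure(list(center = round(as.numeric(center_xy)), size = size,
                 pixel_size_um = pixel_size_um),
            class = "crop_window")
}

#' Crop both channels of a time-lapse around the ablation region
#'
#' Extracts a `size x size` window centred on the ablation-segment midpoint
#' from every frame of both channels. Pixels of the window falling outside
#' the frame are marked missing (`NA`).
#'
#' @param tl a [timelapse()], typically corrected and registered.
#' @param window optional [crop_window()]; by default built from the
#'   time-lapse metadata (ablation midpoint, `crop_size`).
#' @return list with `reporter` and `actin` cropped stacks, `window`, and
#'   `ablation_segment_crop` (segment endpoints in crop coordinates).
#' @export
crop_roi <- function(tl, window = NULL) {
  stopifnot(inherits(tl, "timelapse"))
  if (is.null(window)) {
    window <- crop_window(colMeans(tl$meta$ablation_roi),
                          size = tl$meta$crop_size,
                          pixel_size_um = tl$meta$pixel_size_um)
  }
  seg <- sweep(tl$meta$ablation_roi, 2,
               window$center - (window$size + 1) / 2)
  list(
    reporter = crop_stack(tl$reporter, window),
    actin = crop_stack(tl$actin, window),
    window = window,
    ablation_segment_crop = seg
  )
}

#' Crop a single stack to a window
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param window a [crop_window()].
#' @return `size x size x frames` array; out-of-bounds pixels `NA`.
#' @export
crop_stack <- function(stack, window) {
  stopifnot(is.array(stack), length(dim(stack)) == 3,
            inherits(window, "crop_window"))
  nr <- dim(stack)[1]
  nc <- dim(stack)[2]
  half <- (window$size - 1L) / 2L
  rows <- (window$center[2] - half):(window$center[2] + half)
  cols <- (window$center[1] - half):(window$center[1] + half)
  if (all(rows < 1 | rows > nr) || all(cols < 1 | cols > nc)) {
    stop("crop_stack: window fully outside the frame")
  }
  out <- array(NA_real_, c(window$size, window$size, dim(stack)[3]))
  rin <- rows >= 1 & rows <= nr
  cin <- cols >= 1 & cols <= nc
  out[rin, cin, ] <- stack[rows[rin], cols[cin], , drop = FALSE]
  out
}

#' Pre-ablation reference image
#'
#' Per-pixel mean over the frames strictly before the ablation event,
#' ignoring missing values.
#'
#' @param cropped_stack 3-D numeric array `[row, col, frame]`.
#' @param ablation_frame 1-based index of the first post-ablation frame;
#'   frames `1:(ablation_frame - 1)` form the baseline (at least 2 required).
#' @return matrix with attribute `n_frames_used`.
#' @export
make_reference <- function(cropped_stack, ablation_frame) {
  stopifnot(is.array(cropped_stack), length(dim(cropped_stack)) == 3)
  n_pre <- ablation_frame - 1L
  if (n_pre < 2) stop("insufficient_baseline")
  ref <- frame_mean_image(cropped_stack[, , seq_len(n_pre), drop = FALSE])
  ref[is.nan(ref)] <- NA_real_
  attr(ref, "n_frames_used") <- n_pre
  ref
}

#' Relative difference against the reference image
#'
#' Computes `(frame - reference) / reference` per pixel and frame. Pixels
#' where the reference is at or below `epsilon` are marked missing rather
#' than producing unbounded values.
#'
#' @param cropped_stack 3-D numeric array `[row, col, frame]`.
#' @param reference image from [make_reference()].
#' @param epsilon divisor floor; default `1e-6 * median(reference)`.
#' @return 3-D array of relative differences with `NA` where undefined.
#' @export
relative_difference <- function(cropped_stack, reference, epsilon = NULL) {
  stopifnot(is.array(cropped_stack), length(dim(cropped_stack)) == 3,
            all(dim(cropped_stack)[1:2] == dim(reference)))
  if (is.null(epsilon)) {
    epsilon <- 1e-6 * stats::median(reference, na.rm = TRUE)
  }
  ref <- unclass(reference)
  ref[!is.na(ref) & ref <= epsilon] <- NA_real_
  sweep(cropped_stack, c(1, 2), ref, function(f, r) (f - r) / r)
}

#' Brightest-fraction mask of a single relative-difference frame
#'
#' Selects exactly `k = round(fraction * n_valid)` pixels with the largest
#' relative-difference values. Ties at the threshold are broken by a fixed
#' total order: value (descending), then row-major pixel index (ascending),
#' so the output is deterministic.
#'
#' @param reldiff_frame numeric matrix (reporter-channel relative
#'   difference); `NA` pixels are invalid and never selected.
#' @param fraction fraction of valid pixels to select (default 0.05, the
#'   brightest 5%).
#' @return logical matrix with attribute `k`.
#' @export
top_fraction_mask <- function(reldiff_frame, fraction = 0.05) {
  stopifnot(is.matrix(reldiff_frame), fraction > 0, fraction <= 1)
  nr <- nrow(reldiff_frame)
  nc <- ncol(reldiff_frame)
  v <- as.vector(reldiff_frame) # column-major
  valid <- which(is.finite(v))
  n_valid <- length(valid)
  if (n_valid < 20) stop("top_fraction_mask: fewer than 20 valid pixels")
  k <- round(fraction * n_valid)
  # row-major index of column-major position i (0-based: r * nc + c)
  r0 <- (valid - 1L) %% nr
  c0 <- (valid - 1L) %/% nr
  rm_idx <- r0 * nc + c0
  sel <- valid[order(-v[valid], rm_idx)][seq_len(k)]
  mask <- matrix(FALSE, nr, nc)
  mask[sel] <- TRUE
  attr(mask, "k") <- k
  mask
}

#' Per-time-point brightest-fraction mask series
#'
#' Applies [top_fraction_mask()] to every frame of a reporter-channel
#' relative-difference stack (masks are computed at every time point,
#' pre-ablation frames included).
#'
#' @param reldiff_reporter 3-D array from [relative_difference()] of the
#'   reporter channel.
#' @param fraction brightest fraction (default 0.05).
#' @return logical 3-D array of class `mask_series` with attributes
#'   `fraction` and `k` (per-frame cardinality).
#' @export
mask_series <- function(reldiff_reporter, fraction = 0.05) {
  stopifnot(is.array(reldiff_reporter), length(dim(reldiff_reporter)) == 3)
  nt <- dim(reldiff_reporter)[3]
  masks <- array(FALSE, dim(reldiff_reporter))
  k <- integer(nt)
  for (i in seq_len(nt)) {
    m <- top_fraction_mask(reldiff_reporter[, , i], fraction)
    masks[, , i] <- m
    k[i] <- attr(m, "k")
  }
  structure(masks, fraction = fraction, k = k, class = "mask_series")
}

#' Recruitment trace: masked-mean relative difference over time
#'
#' For every time point, averages the relative difference over the pixels of
#' the reporter-derived brightest-fraction mask, in both channels (the same
#' mask is applied to reporter and actin). The time axis is relative to the
#' ablation (first post-ablation frame at 0 s). A fold-change column
#' (`1 + relative difference`) is emitted alongside.
#'
#' @param reldiff_reporter,reldiff_actin relative-difference stacks.
#' @param masks a [mask_series()] built from `reldiff_reporter`.
#' @param time_s per-frame times in seconds relative to ablation.
#' @param video_id identifier copied into the trace.
#' @return data frame of class `recruitment_trace` with columns `time_s`,
#'   `rel_diff_reporter`, `rel_diff_actin`, `fold_reporter`, `fold_actin`,
#'   `video_id`.
#' @export
extract_trace <- function(reldiff_reporter, reldiff_actin, masks, time_s,
                          video_id = "video1") {
  stopifnot(
    all(dim(reldiff_reporter) == dim(masks)),
    all(dim(reldiff_actin) == dim(masks)),
    length(time_s) == dim(masks)[3],
    !is.unsorted(time_s, strictly = TRUE)
  )
  nt <- dim(masks)[3]
  rep_mean <- act_mean <- numeric(nt)
  for (i in seq_len(nt)) {
    m <- masks[, , i]
    if (!any(m)) stop("extract_trace: empty mask at time point ", i)
    rep_mean[i] <- mean(reldiff_reporter[, , i][m], na.rm = TRUE)
    act_mean[i] <- mean(reldiff_actin[, , i][m], na.rm = TRUE)
  }
  out <- data.frame(
    time_s = time_s,
    rel_diff_reporter = rep_mean,
    rel_diff_actin = act_mean,
    fold_reporter = 1 + rep_mean,
    fold_actin = 1 + act_mean,
    video_id = video_id
  )
  class(out) <- c("recruitment_trace", "data.frame")
  out
}

#' Average traces across videos
#'
#' Resamples every trace onto the time grid of the first by nearest-time
#' matching (tolerance half the median frame interval) and returns the
#' per-time-point mean and sample standard deviation across videos for both
#' channels. With a single trace the standard deviation is 0 by convention.
#'
#' @param traces list of [extract_trace()] results.
#' @param tol_s matching tolerance in seconds; default half the median grid
#'   spacing of the first trace.
#' @return data frame of class `trace_ensemble` with columns `time_s`,
#'   `mean_reporter`, `sd_reporter`, `mean_actin`, `sd_actin`, `n_videos`.
#' @export
aggregate_traces <- function(traces, tol_s = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1)
  grid <- traces[[1]]$time_s
  if (is.null(tol_s)) tol_s <- stats::median(diff(grid)) / 2
  vals_rep <- vals_act <- matrix(NA_real_, length(grid), length(traces))
  for (j in seq_along(traces)) {
    tr <- traces[[j]]
    idx <- vapply(grid, function(t0) which.min(abs(tr$time_s - t0)), integer(1))
    if (any(abs(tr$time_s[idx] - grid) > tol_s)) {
      stop("aggregate_traces: incompatible time grids beyond tolerance")
    }
    vals_rep[, j] <- tr$rel_diff_reporter[idx]
    vals_act[, j] <- tr$rel_diff_actin[idx]
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- data.frame(
    time_s = grid,
    mean_reporter = rowMeans(vals_rep),
    sd_reporter = apply(vals_rep, 1, sd0),
    mean_actin = rowMeans(vals_act),
    sd_actin = apply(vals_act, 1, sd0),
    n_videos = length(traces)
  )
  class(out) <- c("trace_ensemble", "data.frame")
  out
}

#' Plateau estimate of a recruitment trace
#'
#' Mean relative difference over the tail of the post-ablation window, where
#' a saturating recruitment has levelled off.
#'
#' @param trace a `recruitment_trace` or `trace_ensemble`.
#' @param channel `"reporter"` or `"actin"`.
#' @param tail_fraction fraction of the post-ablation rows (largest times)
#'   averaged; default the last third.
#' @return scalar plateau estimate (relative difference units).
#' @export
trace_plateau <- function(trace, channel = c("reporter", "actin"),
                          tail_fraction = 1 / 3) {
  channel <- match.arg(channel)
  col <- if (inherits(trace, "trace_ensemble")) {
    paste0("mean_", channel)
  } else {
    paste0("rel_diff_", channel)
  }
  post <- trace[trace$time_s >= 0, col]
  n <- length(post)
  stopifnot(n >= 1)
  n_tail <- max(1L, floor(n * tail_fraction))
  mean(post[(n - n_tail + 1):n])
}

#' Spatial recruitment-probability map
#'
#' Per-pixel fraction of time points, pooled across videos, at which the
#' pixel belongs to the brightest-fraction mask. By default only
#' post-ablation time points are counted. With `per_video = TRUE` a per-video
#' occupancy map is computed first and the maps averaged, giving every video
#' equal weight regardless of its frame count.
#'
#' @param mask_series_list list of [mask_series()] arrays sharing crop
#'   geometry.
#' @param ablation_frames integer vector, per video, of the first
#'   post-ablation frame (required when `post_only`).
#' @param post_only count post-ablation time points only (default `TRUE`).
#' @param per_video average per-video maps instead of pooled counting.
#' @param pixel_size_um pixel size of the crop.
#' @param ablation_segment 2 x 2 matrix of segment endpoints in crop
#'   coordinates, for map geometry.
#' @param strain_radius_um radius of the strain-region disc, centred on the
#'   crop centre; default half the 5 um ablation segment plus a 1 um margin.
#' @return list of class `spatial_probability_map`: `prob` (matrix in
#'   `[0, 1]`), `n_timepoints`, `strain_radius_um`, `pixel_size_um`,
#'   `ablation_segment`.
#' @export
spatial_probability <- function(mask_series_list, ablation_frames = NULL,
                                post_only = TRUE, per_video = FALSE,
                                pixel_size_um = 0.173,
                                ablation_segment = NULL,
                                strain_radius_um = 3.5) {
  stopifnot(is.list(mask_series_list), length(mask_series_list) >= 1)
  dims <- dim(mask_series_list[[1]])[1:2]
  if (post_only && is.null(ablation_frames)) {
    stop("spatial_probability: ablation_frames required when post_only")
  }
  counts <- matrix(0, dims[1], dims[2])
  total <- 0L
  per_video_maps <- list()
  for (j in seq_along(mask_series_list)) {
    ms <- mask_series_list[[j]]
    stopifnot(all(dim(ms)[1:2] == dims))
    sel <- if (post_only) ablation_frames[j]:dim(ms)[3] else seq_len(dim(ms)[3])
    cnt <- rowSums(ms[, , sel, drop = FALSE], dims = 2)
    if (per_video) per_video_maps[[j]] <- cnt / length(sel)
    counts <- counts + cnt
    total <- total + length(sel)
  }
  prob <- if (per_video) {
    Reduce(`+`, per_video_maps) / length(per_video_maps)
  } else {
    counts / total
  }
  structure(list(
    prob = prob, n_timepoints = total,
    strain_radius_um = strain_radius_um,
    pixel_size_um = pixel_size_um,
    ablation_segment = ablation_segment
  ), class = "spatial_probability_map")
}

#' Strain-region probability fraction and enrichment classification
#'
#' Sums the spatial probability inside the strain-region disc (centred on the
#' crop centre, i.e. the ablation midpoint) as a fraction of the total, and
#' classifies the map by comparison with the disc's area fraction `a`:
#' `inside_enriched` if the fraction exceeds `factor * a`, `outside_enriched`
#' if it falls below `a / factor`, otherwise `random`.
#'
#' @param map a [spatial_probability()] result.
#' @param radius_um disc radius; default `map$strain_radius_um`.
#' @param factor classification factor `c` (default 2).
#' @return list: `inside_fraction`, `area_fraction`, `classification`.
#' @export
strain_region_fraction <- function(map, radius_um = NULL, factor = 2) {
  stopifnot(inherits(map, "spatial_probability_map"), factor > 1)
  if (is.null(radius_um)) radius_um <- map$strain_radius_um
  if (radius_um <= 0) stop("strain_region_fraction: degenerate region")
  nr <- nrow(map$prob)
  nc <- ncol(map$prob)
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  r_px <- radius_um / map$pixel_size_um
  d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
  inside <- d2 <= r_px^2
  total <- sum(map$prob)
  if (total <= 0) stop("strain_region_fraction: empty probability map")
  inside_fraction <- sum(map$prob[inside]) / total
  a <- sum(inside) / (nr * nc)
  classification <- if (inside_fraction > factor * a) {
    "inside_enriched"
  } else if (inside_fraction < a / factor) {
    "outside_enriched"
  } else {
    "random"
  }
  list(inside_fraction = inside_fraction, area_fraction = a,
       classification = classification)
}
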