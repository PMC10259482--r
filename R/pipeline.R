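#' Full recruitment quantification of one time-lapse
#'
#' Runs the complete analysis chain on a two-channel time-lapse, in the order
#' split channels -> flat-field -> photobleach -> register reporter ->
#' propagate shifts to actin -> crop -> reference -> relative difference ->
#' brightest-fraction mask -> trace.
#'
#' The photobleach fit excludes a disc of radius `exclude_margin_um` around
#' the ablation segment so that local recruitment and actin depletion do not
#' bias the global bleach estimate; if the exponential fit fails the ratio
#' fallback ([correct_bleach_ratio()]) is used and noted in the result.
#'
#' Registration shifts are estimated before the bleach correction is applied
#' (phase correlation is exactly invariant to a per-frame scalar rescaling,
#' so the estimates are unaffected) and the bleach exclusion disc is
#' translated by the estimated shift of each frame. With a static disc the
#' drifting scene slides in and out of the kept region, putting a
#' drift-proportional trend into the frame means that the correction then
#' imprints uniformly on every pixel of the relative-difference stack.
#'
#' @param tl a [timelapse()].
#' @param fraction brightest-mask fraction (default 0.05).
#' @param crop_size odd crop side in pixels; default from the metadata (121).
#' @param upsample_factor registration precision (default 100).
#' @param flatfield_sigma_um pseudo-flat-field blur scale (default 10 um).
#' @param exclude_margin_um radius around the ablation segment excluded from
#'   the bleach fit (default 6 um).
#' @param epsilon relative-difference divisor floor; default
#'   `1e-6 * median(reference)`.
#' @param strain_radius_um strain-region disc radius for the spatial map
#'   (default 3.5 um: half the 5 um ablation segment plus a 1 um margin).
#' @param video_id identifier for the trace.
#' @return list of class `recruitment_run`: `trace`, `masks`
#'   ([mask_series()]), `shifts`, `bleach` (per-channel models or
#'   `"ratio_fallback"`), `window`, `ablation_segment_crop`,
#'   `ablation_frame`, `params`.
#' @export
quantify_recruitment <- function(tl, fraction = 0.05, crop_size = NULL,
                                 upsample_factor = 100L,
                                 flatfield_sigma_um = 10,
                                 exclude_margin_um = 6,
                                 epsilon = NULL,
                                 strain_radius_um = 3.5,
                                 video_id = "video1") {
  stopifnot(inherits(tl, "timelapse"))
  meta <- tl$meta
  if (is.null(crop_size)) crop_size <- meta$crop_size
  times <- meta$frame_times_s
  abl <- meta$ablation_frame

  # flat-field, then photobleach (correction order fixed by the pipeline).
  # The pseudo-flat-field is estimated from the temporal mean of ALL frames,
  # so its smooth specimen component sits at the specimen's mean drift
  # position. Because that component belongs to the specimen, the gain is
  # applied in specimen coordinates: frame t is divided by the gain
  # translated to the frame's estimated drift. The divisor field is then
  # identical for every frame in specimen coordinates and cancels exactly in
  # the later relative difference; a gain left static in camera coordinates
  # would instead leave a drift-proportional residual at the blurred fiber
  # ridge.
  ff_r <- estimate_flatfield(tl$reporter, flatfield_sigma_um,
                             meta$pixel_size_um)
  ff_a <- estimate_flatfield(tl$actin, flatfield_sigma_um,
                             meta$pixel_size_um)

  # shifts are estimated from the statically flat-fielded reporter before
  # the bleach correction (a per-frame scalar does not change phase
  # correlation), so both the drift-aligned gain and the bleach exclusion
  # disc can track the drifting scene
  reg <- register_series(apply_flatfield(tl$reporter, ff_r),
                         ablation_frame = abl,
                         upsample_factor = upsample_factor)
  nt <- dim(tl$reporter)[3]
  s_bar <- c(mean(reg$shifts$dy_px), mean(reg$shifts$dx_px))
  apply_flatfield_tracked <- function(stack, ff) {
    g <- unclass(ff)
    out <- stack
    for (i in seq_len(nt)) {
      dy <- reg$shifts$dy_px[i] - s_bar[1]
      dx <- reg$shifts$dx_px[i] - s_bar[2]
      g_i <- fourier_shift(g, dy, dx)
      if (any(g_i <= 0)) g_i <- g # degenerate translation: keep static gain
      out[, , i] <- stack[, , i] / g_i
    }
    out
  }
  rep_c <- apply_flatfield_tracked(tl$reporter, ff_r)
  act_c <- apply_flatfield_tracked(tl$actin, ff_a)
  margin_px <- exclude_margin_um / meta$pixel_size_um
  exclude <- array(FALSE, dim(rep_c))
  for (i in seq_len(nt)) {
    s <- c(reg$shifts$dx_px[i], reg$shifts$dy_px[i]) # (x, y) displacement
    d_roi <- segment_distance_map(dim(rep_c)[1], dim(rep_c)[2],
                                  meta$ablation_roi[1, ] + s,
                                  meta$ablation_roi[2, ] + s)
    exclude[, , i] <- d_roi <= margin_px
  }

  # the bleach model is a global per-frame scalar, so it is fitted on the
  # raw channel (whose frame means are free of scene-gain coupling under
  # drift; the gain map has unit mean) and applied to the flat-fielded stack
  correct_channel <- function(raw, stack) {
    model <- tryCatch(fit_bleach(raw, times, exclude), error = function(e) e)
    if (inherits(model, "error")) {
      m <- vapply(seq_len(nt), function(i) {
        mean(raw[, , i][!exclude[, , i]], na.rm = TRUE)
      }, numeric(1))
      if (any(m <= 0)) stop("correct_bleach_ratio: non-positive frame mean")
      list(stack = sweep(stack, 3, m[1] / m, "*"), model = "ratio_fallback")
    } else {
      list(stack = correct_bleach(stack, model, times), model = model)
    }
  }
  bc_r <- correct_channel(tl$reporter, rep_c)
  bc_a <- correct_channel(tl$actin, act_c)

  rep_reg <- apply_shifts(bc_r$stack, reg$shifts)
  act_reg <- apply_shifts(bc_a$stack, reg$shifts)

  window <- crop_window(colMeans(meta$ablation_roi), size = crop_size,
                        pixel_size_um = meta$pixel_size_um)
  rep_crop <- crop_stack(rep_reg, window)
  act_crop <- crop_stack(act_reg, window)
  seg_crop <- sweep(meta$ablation_roi, 2, window$center - (crop_size + 1) / 2)

  ref_r <- make_reference(rep_crop, abl)
  ref_a <- make_reference(act_crop, abl)
  rd_r <- relative_difference(rep_crop, ref_r, epsilon)
  rd_a <- relative_difference(act_crop, ref_a, epsilon)

  masks <- mask_series(rd_r, fraction)
  trace <- extract_trace(rd_r, rd_a, masks, times - times[abl], video_id)

  structure(list(
    trace = trace, masks = masks, shifts = reg$shifts,
    bleach = list(reporter = bc_r$model, actin = bc_a$model),
    window = window, ablation_segment_crop = seg_crop,
    ablation_frame = abl, strain_radius_um = strain_radius_um,
    pixel_size_um = meta$pixel_size_um,
    params = list(fraction = fraction, crop_size = crop_size,
                  upsample_factor = upsample_factor,
                  flatfield_sigma_um = flatfield_sigma_um,
                  exclude_margin_um = exclude_margin_um,
                  strain_radius_um = strain_radius_um)
  ), class = "recruitment_run")
}

#' Aggregate several recruitment runs into ensemble trace and spatial map
#'
#' @param runs list of [quantify_recruitment()] results sharing crop
#'   geometry.
#' @param post_only restrict the spatial map to post-ablation time points.
#' @param per_video average per-video occupancy maps instead of pooled
#'   counting.
#' @return list: `ensemble` ([aggregate_traces()]), `map`
#'   ([spatial_probability()]), `strain` ([strain_region_fraction()]).
#' @export
aggregate_runs <- function(runs, post_only = TRUE, per_video = FALSE) {
  stopifnot(length(runs) >= 1)
  ensemble <- aggregate_traces(lapply(runs, `[[`, "trace"))
  map <- spatial_probability(
    lapply(runs, `[[`, "masks"),
    ablation_frames = vapply(runs, `[[`, integer(1), "ablation_frame"),
    post_only = post_only, per_video = per_video,
    pixel_size_um = runs[[1]]$pixel_size_um,
    ablation_segment = runs[[1]]$ablation_segment_crop,
    strain_radius_um = runs[[1]]$strain_radius_um
  )
  list(ensemble = ensemble, map = map, strain = strain_region_fraction(map))
}

default_run_params <- function() {
  # crop_size NA: use each stack's own metadata (121 for generator defaults)
  list(fraction = 0.05, crop_size = NA_integer_, upsample_factor = 100L,
       flatfield_sigma_um = 10, exclude_margin_um = 6,
       strain_radius_um = 3.5, edge_threshold = 0.9, smooth = 5L,
       classification_factor = 2)
}

merge_run_params <- function(overrides) {
  params <- default_run_params()
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  params[names(overrides)] <- overrides
  params
}

#' Run the recruitment pipeline end to end from a configuration
#'
#' Reads a time-lapse (from `input_dir`, as written by [write_timelapse()],
#' or passed directly), runs [quantify_recruitment()] on each video,
#' aggregates, and writes the trace CSVs, the shift CSV, the spatial
#' probability map (TIFF + JSON), and a machine-readable run report (all
#' parameters plus MD5 checksums of every output).
#'
#' @param input either a [timelapse()], a list of them, or a character vector
#'   of directories readable by [read_timelapse()].
#' @param out_dir output directory.
#' @param params named list overriding [default_run_params()]; unknown keys
#'   are rejected.
#' @return invisibly, the run report (also written to `report.json`).
#' @export
run_recruitment_pipeline <- function(input, out_dir, params = list()) {
  p <- merge_run_params(params)
  tls <- if (inherits(input, "timelapse")) {
    list(input)
  } else if (is.character(input)) {
    lapply(input, read_timelapse)
  } else {
    input
  }
  stopifnot(all(vapply(tls, inherits, logical(1), "timelapse")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  runs <- lapply(seq_along(tls), function(i) {
    quantify_recruitment(
      tls[[i]],
      fraction = p$fraction,
      crop_size = if (is.na(p$crop_size)) NULL else p$crop_size,
      upsample_factor = p$upsample_factor,
      flatfield_sigma_um = p$flatfield_sigma_um,
      exclude_margin_um = p$exclude_margin_um,
      strain_radius_um = p$strain_radius_um,
      video_id = sprintf("video%02d", i)
    )
  })
  agg <- aggregate_runs(runs)

  traces <- do.call(rbind, lapply(runs, `[[`, "trace"))
  write_csv_out(traces, file.path(out_dir, "traces.csv"))
  write_csv_out(agg$ensemble, file.path(out_dir, "trace_ensemble.csv"))
  shifts <- do.call(rbind, lapply(seq_along(runs), function(i) {
    cbind(video_id = sprintf("video%02d", i),
          as.data.frame(runs[[i]]$shifts))
  }))
  write_csv_out(shifts, file.path(out_dir, "shifts.csv"))
  write_probability_map(agg$map, file.path(out_dir, "spatial_probability.tif"),
                        file.path(out_dir, "spatial_probability.json"))

  outputs <- file.path(out_dir, c("traces.csv", "trace_ensemble.csv",
                                  "shifts.csv", "spatial_probability.tif",
                                  "spatial_probability.json"))
  report <- list(
    pipeline = "recruitment",
    n_videos = length(runs),
    params = p,
    plateau_reporter = trace_plateau(agg$ensemble, "reporter"),
    plateau_actin = trace_plateau(agg$ensemble, "actin"),
    strain = agg$strain,
    bleach = lapply(runs, function(r) {
      lapply(r$bleach, function(b) {
        if (is.character(b)) b else b[c("amplitude", "tau", "offset",
                                        "fit_residual")]
      })
    }),
    checksums = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the gap pipeline end to end from CSV inputs
#'
#' Computes the per-gap enrichment ratios (one per `organ_id` x `cell_id`
#' group of the line-scan CSV), aggregates them per organ, and summarizes the
#' count table into gap frequency, dead-cell percentage, and mean stereocilia
#' per cell; writes per-organ CSVs and a run report.
#'
#' @param linescan_csv path to a line-scan CSV (optional).
#' @param counts_csv path to a count-table CSV (optional).
#' @param out_dir output directory.
#' @param params named list overriding [default_run_params()] (`smooth`,
#'   `edge_threshold` are used here).
#' @return invisibly, the run report.
#' @export
run_gap_pipeline <- function(linescan_csv = NULL, counts_csv = NULL, out_dir,
                             params = list()) {
  p <- merge_run_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  report <- list(pipeline = "gaps", params = p)

  if (!is.null(linescan_csv)) {
    scans <- read_linescan_csv(linescan_csv)
    if (!"organ_id" %in% names(scans)) scans$organ_id <- "organ1"
    if (!"cell_id" %in% names(scans)) scans$cell_id <- "cell1"
    groups <- split(scans, list(scans$organ_id, scans$cell_id), drop = TRUE)
    calls <- lapply(groups, function(g) {
      enrichment_ratio(g, smooth = p$smooth, edge_threshold = p$edge_threshold)
    })
    ratios <- data.frame(
      organ_id = vapply(calls, function(cl) as.character(cl$organ_id),
                        character(1)),
      cell_id = vapply(calls, function(cl) as.character(cl$cell_id),
                       character(1)),
      enrichment_ratio = vapply(calls, `[[`, numeric(1), "enrichment_ratio")
    )
    ratios <- ratios[order(ratios$organ_id, ratios$cell_id), ]
    per_organ <- aggregate_enrichment(ratios)
    write_csv_out(ratios, file.path(out_dir, "enrichment_calls.csv"))
    write_csv_out(per_organ, file.path(out_dir, "enrichment_per_organ.csv"))
    outputs <- c(outputs, file.path(out_dir, c("enrichment_calls.csv",
                                               "enrichment_per_organ.csv")))
    report$enrichment <- per_organ
  }

  if (!is.null(counts_csv)) {
    tab <- read_count_csv(counts_csv)
    gf <- gap_frequency(tab)
    dc <- dead_cell_percent(tab)
    sm <- stereocilia_mean(tab)
    write_csv_out(gf, file.path(out_dir, "gap_frequency.csv"))
    write_csv_out(dc, file.path(out_dir, "dead_cell_percent.csv"))
    write_csv_out(sm, file.path(out_dir, "stereocilia_mean.csv"))
    outputs <- c(outputs, file.path(out_dir, c("gap_frequency.csv",
                                               "dead_cell_percent.csv",
                                               "stereocilia_mean.csv")))
    report$gap_frequency <- gf
    report$dead_cell_percent <- dc
    report$stereocilia_mean <- sm
  }

  report$checksums <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
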