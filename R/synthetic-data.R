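#' Simulation configuration for synthetic ablation time-lapses
#'
#' Bundles and validates all parameters of the synthetic two-channel
#' (actin + reporter) time-lapse generator. Defaults emulate a typical
#' acquisition: a 3.5 min movie at one frame pair every 2 s, 30 s of
#' steady-state baseline before a 5 um linear photoablation on a stress
#' fiber, at 0.173 um/pixel (so a 121 px crop spans ~21 um).
#'
#' @param image_size integer vector `c(rows, cols)` in pixels.
#' @param pixel_size pixel size in um/pixel.
#' @param n_pre_frames number of pre-ablation frames (>= 2).
#' @param n_post_frames number of post-ablation frames.
#' @param frame_interval frame spacing in seconds (> 0).
#' @param fiber_endpoints 2 x 2 matrix, rows = the two endpoints, columns =
#'   (x, y) pixel coordinates of the stress fiber; default a horizontal fiber
#'   through the image centre spanning 70% of the width.
#' @param fiber_width Gaussian full width of the fiber cross-section in
#'   pixels (profile `exp(-d^2 / (2 * (fiber_width / 2)^2))`).
#' @param fiber_intensity peak fiber intensity, arbitrary units.
#' @param background_intensity cytoplasmic background intensity.
#' @param bleach_tau photobleaching time constant in seconds (`Inf` disables
#'   bleaching).
#' @param drift_per_frame numeric `c(dy, dx)` rigid drift per frame in pixels
#'   (sub-pixel allowed).
#' @param ablation_roi 2 x 2 matrix as `fiber_endpoints`; default a 5 um
#'   segment centred on the fiber midpoint, along the fiber.
#' @param recruitment_amplitude plateau of the reporter relative difference
#'   inside the recruitment region (dimensionless, >= 0).
#' @param recruitment_halftime half-time of the saturating-exponential
#'   recruitment rise, seconds.
#' @param recruitment_radius radius around the ablation segment that recruits
#'   reporter, in um.
#' @param recruitment_inner_radius inner radius in um below which no reporter
#'   is recruited (default 0: recruitment fills the region up to the segment).
#'   A positive value produces an annular band between the inner and outer
#'   radius, emulating constructs recruited around, rather than onto, the
#'   strained zone. Must leave at least 1 um of band:
#'   `recruitment_inner_radius + 1 <= recruitment_radius`.
#' @param actin_depletion_fraction fraction of actin signal lost inside the
#'   ablation zone, in `[0, 1]`.
#' @param texture_amplitude relative sd of the static multiplicative
#'   cytoplasmic texture shared by both channels (granularity/organelles;
#'   gives whole-image registration its signal away from the fiber axis).
#' @param texture_sigma_um correlation length of the coarse texture, um.
#' @param texture_fine_amplitude relative sd of the static diffraction-scale
#'   speckle component (correlation length `psf_sigma_um`), which fills the
#'   upper spatial-frequency band as real label granularity does.
#' @param psf_sigma_um Gaussian point-spread sigma of the fine speckle, um.
#' @param noise_model `"gaussian"` (multiplicative, sd relative to the local
#'   noise-free signal) or `"poisson"` (shot noise, `poisson_scale` expected
#'   photons per intensity unit).
#' @param gaussian_sd relative standard deviation of the Gaussian noise
#'   (e.g. 0.02 for 2% of the local signal). 0 disables noise.
#' @param poisson_scale photons per intensity unit for the Poisson model.
#' @param crop_size analysis crop size in pixels (odd); recorded in the
#'   metadata and used to validate that the image can host the crop.
#' @param seed integer RNG seed; identical seed and configuration give
#'   bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(image_size = c(512L, 512L),
                       pixel_size = 0.173,
                       n_pre_frames = 15L,
                       n_post_frames = 90L,
                       frame_interval = 2.0,
                       fiber_endpoints = NULL,
                       fiber_width = 4,
                       fiber_intensity = 400,
                       background_intensity = 100,
                       bleach_tau = 200,
                       drift_per_frame = c(0, 0),
                       ablation_roi = NULL,
                       recruitment_amplitude = 0.5,
                       recruitment_halftime = 15,
                       recruitment_radius = 2.0,
                       recruitment_inner_radius = 0,
                       actin_depletion_fraction = 0.8,
                       texture_amplitude = 0.1,
                       texture_sigma_um = 1.0,
                       texture_fine_amplitude = 0.05,
                       psf_sigma_um = 0.14,
                       noise_model = c("gaussian", "poisson"),
                       gaussian_sd = 0.02,
                       poisson_scale = 1000,
                       crop_size = 121L,
                       seed = 1L) {
  image_size <- as.integer(rep(image_size, length.out = 2))
  noise_model <- match.arg(noise_model)
  if (is.null(fiber_endpoints)) {
    cx <- (image_size[2] + 1) / 2
    cy <- (image_size[1] + 1) / 2
    half <- 0.35 * image_size[2]
    fiber_endpoints <- rbind(c(cx - half, cy), c(cx + half, cy))
  }
  fiber_endpoints <- as.matrix(fiber_endpoints)
  if (is.null(ablation_roi)) {
    v <- fiber_endpoints[2, ] - fiber_endpoints[1, ]
    u <- v / sqrt(sum(v^2))
    mid <- colMeans(fiber_endpoints)
    half_px <- (5 / pixel_size) / 2 # 5 um ablation segment
    ablation_roi <- rbind(mid - half_px * u, mid + half_px * u)
  }
  ablation_roi <- as.matrix(ablation_roi)

  cfg <- list(
    image_size = image_size, pixel_size = pixel_size,
    n_pre_frames = as.integer(n_pre_frames),
    n_post_frames = as.integer(n_post_frames),
    frame_interval = frame_interval,
    fiber_endpoints = fiber_endpoints, fiber_width = fiber_width,
    fiber_intensity = fiber_intensity,
    background_intensity = background_intensity,
    bleach_tau = bleach_tau,
    drift_per_frame = as.numeric(drift_per_frame),
    ablation_roi = ablation_roi,
    recruitment_amplitude = recruitment_amplitude,
    recruitment_halftime = recruitment_halftime,
    recruitment_radius = recruitment_radius,
    recruitment_inner_radius = recruitment_inner_radius,
    actin_depletion_fraction = actin_depletion_fraction,
    texture_amplitude = texture_amplitude,
    texture_sigma_um = texture_sigma_um,
    texture_fine_amplitude = texture_fine_amplitude,
    psf_sigma_um = psf_sigma_um,
    noise_model = noise_model, gaussian_sd = gaussian_sd,
    poisson_scale = poisson_scale,
    crop_size = as.integer(crop_size), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_pre_frames >= 2L,
    cfg$n_post_frames >= 0L,
    cfg$frame_interval > 0,
    cfg$bleach_tau > 0,
    cfg$recruitment_amplitude >= 0,
    cfg$recruitment_halftime > 0,
    cfg$recruitment_radius > 0,
    cfg$recruitment_inner_radius >= 0,
    cfg$recruitment_inner_radius == 0 ||
      cfg$recruitment_inner_radius + 1 <= cfg$recruitment_radius,
    cfg$actin_depletion_fraction >= 0, cfg$actin_depletion_fraction <= 1,
    cfg$fiber_width > 0, cfg$pixel_size > 0,
    cfg$texture_amplitude >= 0, cfg$texture_sigma_um > 0,
    cfg$texture_fine_amplitude >= 0, cfg$psf_sigma_um > 0,
    cfg$gaussian_sd >= 0, cfg$poisson_scale > 0,
    all(dim(cfg$fiber_endpoints) == c(2, 2)),
    all(dim(cfg$ablation_roi) == c(2, 2)),
    cfg$crop_size %% 2L == 1L
  )
  if (any(cfg$image_size < cfg$crop_size)) stop("image_too_small")
  # the ablation ROI must sit on the fiber
  d <- point_segment_distance(
    cfg$ablation_roi[, 1], cfg$ablation_roi[, 2],
    cfg$fiber_endpoints[1, ], cfg$fiber_endpoints[2, ]
  )
  if (max(d) > cfg$fiber_width) stop("roi_off_fiber")
  invisible(cfg)
}

# Distance from points (x, y) to the segment p1--p2 (all in pixel units).
point_segment_distance <- function(x, y, p1, p2) {
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) {
    return(sqrt((x - p1[1])^2 + (y - p1[2])^2))
  }
  t <- pmin(pmax(((x - p1[1]) * v[1] + (y - p1[2]) * v[2]) / len2, 0), 1)
  sqrt((x - p1[1] - t * v[1])^2 + (y - p1[2] - t * v[2])^2)
}

# Radial profile that is 1 for d <= radius - width, falls as a raised cosine,
# and reaches 0 at d = radius (support strictly inside the radius).
edge_taper <- function(d, radius, width) {
  stopifnot(radius > 0, width > 0, width <= radius)
  inner <- radius - width
  p <- 0.5 * (1 + cos(pi * (d - inner) / width))
  p[d <= inner] <- 1
  p[d >= radius] <- 0
  p
}

# Matrix of distances (px) from every pixel centre to a segment; pixel (r, c)
# has coordinates x = c, y = r.
segment_distance_map <- function(nr, nc, p1, p2) {
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  matrix(point_segment_distance(as.vector(x), as.vector(y), p1, p2), nr, nc)
}

# Evaluate RNG-dependent code under a seed, restoring the global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a two-channel ablation time-lapse with known ground truth
#'
#' Renders a bright linear stress fiber on dim cytoplasm in both channels
#' (the fiber is fainter in the reporter channel), applies global exponential
#' photobleaching and slow rigid drift, then, from the ablation frame onward,
#' locally depletes the actin signal along the ablation segment and raises
#' the reporter signal inside the recruitment region toward
#' `(1 + amplitude) * local baseline` with a saturating-exponential half-time.
#' Noise is added last (multiplicative Gaussian relative to the local
#' noise-free signal, or Poisson shot noise). Drift is applied by Fourier
#' translation with periodic boundary, so frame means are drift-invariant.
#'
#' @param config a [sim_config()].
#' @return list with `timelapse` (class `timelapse`: elements `reporter` and
#'   `actin`, 3-D arrays `[row, col, frame]`, plus `meta`) and `truth`
#'   (injected parameters: per-frame shifts with frame 1 at `(0, 0)`,
#'   bleach tau, recruitment amplitude, recruitment-region pixel mask,
#'   ablation-zone mask).
#' @export
simulate_timelapse <- function(config) {
  cfg <- validate_sim_config(config)
  nr <- cfg$image_size[1]
  nc <- cfg$image_size[2]
  n_pre <- cfg$n_pre_frames
  nt <- n_pre + cfg$n_post_frames
  ablation_frame <- n_pre + 1L

  sigma <- cfg$fiber_width / 2
  d_fiber <- segment_distance_map(nr, nc, cfg$fiber_endpoints[1, ],
                                  cfg$fiber_endpoints[2, ])
  fiber <- exp(-d_fiber^2 / (2 * sigma^2))
  amp <- cfg$fiber_intensity - cfg$background_intensity

  d_roi <- segment_distance_map(nr, nc, cfg$ablation_roi[1, ],
                                cfg$ablation_roi[2, ])
  # recruitment and depletion profiles have diffuse (cosine-tapered) edges,
  # as real protein accumulations do; the support stays within the stated
  # radius, so every recruited pixel lies inside recruitment_radius
  taper_w <- 0.5 / cfg$pixel_size
  recruit_profile <- edge_taper(d_roi, cfg$recruitment_radius / cfg$pixel_size,
                                taper_w)
  if (cfg$recruitment_inner_radius > 0) {
    inner_px <- cfg$recruitment_inner_radius / cfg$pixel_size
    recruit_profile <- recruit_profile *
      (1 - edge_taper(d_roi, inner_px + taper_w, taper_w))
  }
  recruit_region <- recruit_profile > 0
  zone_profile <- edge_taper(d_roi, cfg$fiber_width, min(taper_w, cfg$fiber_width / 2))
  ablation_zone <- zone_profile > 0

  times <- (seq_len(nt) - 1) * cfg$frame_interval
  bleach <- exp(-times / cfg$bleach_tau)
  shifts <- outer(seq_len(nt) - 1, cfg$drift_per_frame) # [frame, (dy,dx)]

  reporter <- array(NA_real_, c(nr, nc, nt))
  actin <- array(NA_real_, c(nr, nc, nt))
  with_seed(cfg$seed, {
    # static cytoplasmic texture, shared by both channels and drifting with
    # the scene; gives whole-image registration 2-D signal as in real cells
    texture <- 1
    if (cfg$texture_amplitude > 0 || cfg$texture_fine_amplitude > 0) {
      norm_tex <- function(t) (t - mean(t)) / stats::sd(t)
      tex <- 0
      if (cfg$texture_amplitude > 0) {
        tex <- tex + cfg$texture_amplitude * norm_tex(gaussian_blur_fft(
          matrix(stats::rnorm(nr * nc), nr, nc),
          cfg$texture_sigma_um / cfg$pixel_size))
      }
      if (cfg$texture_fine_amplitude > 0) {
        tex <- tex + cfg$texture_fine_amplitude * norm_tex(gaussian_blur_fft(
          matrix(stats::rnorm(nr * nc), nr, nc),
          cfg$psf_sigma_um / cfg$pixel_size))
      }
      texture <- pmax(1 + tex, 0.05)
    }
    actin_base <- (cfg$background_intensity + amp * fiber) * texture
    # the reporter construct is mostly cytosolic with weak fiber association
    reporter_base <- (cfg$background_intensity + 0.4 * amp * fiber) * texture

    actin_post <- actin_base * (1 - cfg$actin_depletion_fraction * zone_profile)
    reporter_delta <- reporter_base * cfg$recruitment_amplitude * recruit_profile

    # cached spectra: per frame only one inverse FFT per channel is needed
    f_actin_pre <- fft2(actin_base)
    f_actin_post <- fft2(actin_post)
    f_rep_base <- fft2(reporter_base)
    f_rep_delta <- fft2(reporter_delta)

    for (i in seq_len(nt)) {
      dy <- shifts[i, 1]
      dx <- shifts[i, 2]
      ramp <- if (dy == 0 && dx == 0) 1 else shift_phase_ramp(nr, nc, dy, dx)
      if (i < ablation_frame) {
        f_a <- f_actin_pre
        f_r <- f_rep_base
      } else {
        t_since <- (i - ablation_frame) * cfg$frame_interval
        f_rise <- 1 - exp(-t_since * log(2) / cfg$recruitment_halftime)
        f_a <- f_actin_post
        f_r <- f_rep_base + f_rise * f_rep_delta
      }
      a <- Re(ifft2(f_a * ramp)) * bleach[i]
      r <- Re(ifft2(f_r * ramp)) * bleach[i]
      if (cfg$noise_model == "gaussian" && cfg$gaussian_sd > 0) {
        r <- r * (1 + cfg$gaussian_sd * matrix(stats::rnorm(nr * nc), nr, nc))
        a <- a * (1 + cfg$gaussian_sd * matrix(stats::rnorm(nr * nc), nr, nc))
      } else if (cfg$noise_model == "poisson") {
        r <- matrix(stats::rpois(nr * nc, pmax(r, 0) * cfg$poisson_scale),
                    nr, nc) / cfg$poisson_scale
        a <- matrix(stats::rpois(nr * nc, pmax(a, 0) * cfg$poisson_scale),
                    nr, nc) / cfg$poisson_scale
      }
      reporter[, , i] <- r
      actin[, , i] <- a
    }
  })

  tl <- timelapse(
    reporter = reporter, actin = actin,
    pixel_size_um = cfg$pixel_size,
    frame_interval_s = cfg$frame_interval,
    ablation_frame = ablation_frame,
    ablation_roi = cfg$ablation_roi,
    crop_size = cfg$crop_size,
    seed = cfg$seed
  )
  truth <- list(
    true_shifts = shifts,
    true_bleach_tau = cfg$bleach_tau,
    true_recruitment_amplitude = cfg$recruitment_amplitude,
    true_recruitment_region = recruit_region,
    true_ablation_zone = ablation_zone,
    config = cfg
  )
  list(timelapse = tl, truth = truth)
}

#' Two-channel time-lapse container
#'
#' @param reporter,actin 3-D numeric arrays `[row, col, frame]` with equal
#'   dimensions.
#' @param pixel_size_um,frame_interval_s acquisition geometry and cadence.
#' @param ablation_frame 1-based index of the first post-ablation frame.
#' @param ablation_roi 2 x 2 matrix of segment endpoints, columns (x, y) px.
#' @param crop_size analysis crop size (odd, pixels).
#' @param channel_offset_s acquisition offset between the two channels
#'   (recorded; the analysis treats channels as co-sampled).
#' @param seed seed recorded from the generator, if any.
#' @return object of class `timelapse`.
#' @export
timelapse <- function(reporter, actin, pixel_size_um, frame_interval_s,
                      ablation_frame, ablation_roi, crop_size = 121L,
                      channel_offset_s = frame_interval_s / 2, seed = NA_integer_) {
  stopifnot(
    is.array(reporter), is.array(actin),
    length(dim(reporter)) == 3, all(dim(reporter) == dim(actin)),
    ablation_frame >= 2, ablation_frame <= dim(reporter)[3] + 1
  )
  nt <- dim(reporter)[3]
  meta <- list(
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    frame_times_s = (seq_len(nt) - 1) * frame_interval_s,
    ablation_frame = as.integer(ablation_frame),
    ablation_roi = as.matrix(ablation_roi),
    crop_size = as.integer(crop_size),
    channel_offset_s = channel_offset_s,
    seed = seed
  )
  structure(list(reporter = reporter, actin = actin, meta = meta),
            class = "timelapse")
}

#' @export
print.timelapse <- function(x, ...) {
  d <- dim(x$reporter)
  cat(sprintf(
    "timelapse: %d x %d px, %d frames (%d pre-ablation), %.3g um/px, %.3g s/frame\n",
    d[1], d[2], d[3], x$meta$ablation_frame - 1L, x$meta$pixel_size_um,
    x$meta$frame_interval_s
  ))
  invisible(x)
}

#' Simulate a dual-channel stereocilium line scan with known enrichment
#'
#' The phalloidin (F-actin) channel is a plateau with a centred smooth
#' Gaussian dip of relative depth `gap_depth` (the "gap"); the reporter
#' channel is a plateau carrying a centred flat-topped (raised-cosine
#' tapered) peak whose top sits at `fold` times the plateau and which decays
#' to the plateau well inside the gap edges, so the center/edge enrichment
#' ratio of the noise-free profile equals `fold` exactly.
#'
#' @param fold true fold-enrichment of the reporter at the gap centre (> 0).
#' @param gap_depth relative depth of the phalloidin dip, in `(0, 1]`.
#' @param noise_sd additive Gaussian noise sd, same units as the intensities
#'   (plateaus are 100, so `noise_sd = 2` is 2% of the plateau).
#' @param seed integer RNG seed.
#' @param n number of samples along the scan.
#' @param length_um scan length in um.
#' @param gap_sigma_um Gaussian sigma of the phalloidin dip, um.
#' @param organ_id,cell_id identifiers copied into the profile.
#' @return list with `profile` (data frame: `position_um`, `phalloidin`,
#'   `reporter`, `organ_id`, `cell_id`) and `truth`
#'   (`true_fold_enrichment`, dip geometry).
#' @export
simulate_linescan <- function(fold, gap_depth = 0.6, noise_sd = 0, seed = 1L,
                              n = 81L, length_um = 4, gap_sigma_um = 0.3,
                              organ_id = "organ1", cell_id = "cell1") {
  if (!is.numeric(fold) || fold <= 0) stop("fold must be > 0")
  stopifnot(gap_depth > 0, gap_depth <= 1, noise_sd >= 0, n >= 15)
  plateau <- 100
  pos <- seq(0, length_um, length.out = n)
  centre <- length_um / 2
  u <- abs(pos - centre)
  phalloidin <- plateau * (1 - gap_depth * exp(-u^2 / (2 * gap_sigma_um^2)))
  # flat-topped reporter peak: flat for u <= w1, cosine taper to 0 at w2
  w1 <- 0.5 * gap_sigma_um
  w2 <- 7 * gap_sigma_um / 6
  bump <- ifelse(u <= w1, 1,
                 ifelse(u >= w2, 0, 0.5 * (1 + cos(pi * (u - w1) / (w2 - w1)))))
  reporter <- plateau * (1 + (fold - 1) * bump)
  if (noise_sd > 0) {
    with_seed(seed, {
      phalloidin <- phalloidin + stats::rnorm(n, sd = noise_sd)
      reporter <- reporter + stats::rnorm(n, sd = noise_sd)
    })
  }
  profile <- data.frame(
    position_um = pos, phalloidin = phalloidin, reporter = reporter,
    organ_id = organ_id, cell_id = cell_id
  )
  truth <- list(
    true_fold_enrichment = fold, gap_depth = gap_depth,
    gap_sigma_um = gap_sigma_um, centre_um = centre,
    centre_index = which.min(abs(pos - centre))
  )
  list(profile = profile, truth = truth)
}

#' Simulate a toy gap/death/stereocilia count study
#'
#' Draws per-image counts of cells with gaps and dead cells binomially at the
#' given rates, and total stereocilia as Poisson with a fixed per-cell mean,
#' for one or more organs.
#'
#' @param n_images images per organ.
#' @param cells_per_image cells in every image.
#' @param gap_rate,death_rate per-cell probabilities in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param n_organs number of organs.
#' @param stereocilia_per_cell expected stereocilia per cell (Poisson mean).
#' @return list with `table` (data frame: `organ_id`, `image_id`,
#'   `cells_total`, `cells_with_gaps`, `cells_dead`, `stereocilia_total`) and
#'   `truth` (the injected rates).
#' @export
simulate_count_study <- function(n_images, cells_per_image, gap_rate,
                                 death_rate, seed = 1L, n_organs = 1L,
                                 stereocilia_per_cell = 20) {
  stopifnot(
    n_images >= 1, cells_per_image >= 1,
    gap_rate >= 0, gap_rate <= 1, death_rate >= 0, death_rate <= 1,
    n_organs >= 1, stereocilia_per_cell > 0
  )
  n <- n_images * n_organs
  tab <- with_seed(seed, data.frame(
    organ_id = rep(sprintf("organ%02d", seq_len(n_organs)), each = n_images),
    image_id = rep(sprintf("image%02d", seq_len(n_images)), times = n_organs),
    cells_total = rep.int(as.integer(cells_per_image), n),
    cells_with_gaps = stats::rbinom(n, cells_per_image, gap_rate),
    cells_dead = stats::rbinom(n, cells_per_image, death_rate),
    stereocilia_total = stats::rpois(n, cells_per_image * stereocilia_per_cell)
  ))
  truth <- list(
    true_gap_rate = gap_rate, true_death_rate = death_rate,
    true_stereocilia_per_cell = stereocilia_per_cell,
    true_counts = tab
  )
  list(table = tab, truth = truth)
}
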