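test_that("config validation enforces geometry and invariants", {
  expect_error(quick_config(image_size = c(32L, 32L), crop_size = 41L),
               "image_too_small")
  # ablation segment placed far off the fiber
  expect_error(
    quick_config(ablation_roi = rbind(c(10, 5), c(30, 5))),
    "roi_off_fiber"
  )
  expect_error(quick_config(crop_size = 40L))
  expect_error(quick_config(n_pre_frames = 1L))
  expect_error(quick_config(recruitment_amplitude = -0.1))
  expect_error(quick_config(actin_depletion_fraction = 1.5))
  # annular recruitment must leave at least 1 um of band
  expect_error(quick_config(recruitment_radius = 2,
                            recruitment_inner_radius = 1.5))
})

test_that("same seed and config give bit-identical output", {
  cfg <- quick_config(gaussian_sd = 0.02, drift_per_frame = c(0.2, -0.1),
                      bleach_tau = 100, seed = 7L)
  a <- simulate_timelapse(cfg)
  b <- simulate_timelapse(cfg)
  expect_identical(a$timelapse$reporter, b$timelapse$reporter)
  expect_identical(a$timelapse$actin, b$timelapse$actin)
  expect_identical(a$truth$true_shifts, b$truth$true_shifts)
  # different seed changes the noise realization
  cfg2 <- quick_config(gaussian_sd = 0.02, drift_per_frame = c(0.2, -0.1),
                       bleach_tau = 100, seed = 8L)
  expect_false(identical(simulate_timelapse(cfg2)$timelapse$reporter,
                         a$timelapse$reporter))
})

test_that("no noise, no drift, no bleach: pre-ablation frames are static", {
  sim <- simulate_timelapse(quick_config())
  pre <- sim$timelapse$reporter[, , 1:5]
  for (i in 2:5) expect_identical(pre[, , i], pre[, , 1])
  pre_a <- sim$timelapse$actin[, , 1:5]
  for (i in 2:5) expect_identical(pre_a[, , i], pre_a[, , 1])
})

test_that("frame means decay as exp(-t/tau) with noise 0", {
  tau <- 60
  cfg <- quick_config(bleach_tau = tau, recruitment_amplitude = 0,
                      actin_depletion_fraction = 0, n_post_frames = 10L)
  sim <- simulate_timelapse(cfg)
  times <- sim$timelapse$meta$frame_times_s
  m <- apply(sim$timelapse$reporter, 3, mean)
  expect_equal(m / m[1], exp(-times / tau), tolerance = 1e-6)
})

test_that("integer drift is an exact circular translation", {
  cfg <- quick_config(drift_per_frame = c(1, 0), n_pre_frames = 6L,
                      n_post_frames = 0L)
  sim <- simulate_timelapse(cfg)
  r <- sim$timelapse$reporter
  for (k in 2:6) {
    expect_equal(r[, , k], circ_shift(r[, , 1], k - 1, 0), tolerance = 1e-9)
  }
  expect_equal(sim$truth$true_shifts[1, ], c(0, 0))
  expect_equal(nrow(sim$truth$true_shifts), 6)
})

test_that("sub-pixel drift matches an independent Fourier-shift oracle", {
  cfg <- quick_config(drift_per_frame = c(0.5, 0), n_pre_frames = 6L,
                      n_post_frames = 0L)
  sim <- simulate_timelapse(cfg)
  r <- sim$timelapse$reporter
  rng <- diff(range(r[, , 1]))
  for (k in c(2L, 4L, 6L)) {
    oracle <- oracle_fourier_shift(r[, , 1], 0.5 * (k - 1), 0)
    expect_lt(max(abs(r[, , k] - oracle)), 0.01 * rng)
  }
})

test_that("recruited pixels all lie within recruitment_radius of the segment", {
  cfg <- quick_config()
  sim <- simulate_timelapse(cfg)
  region <- sim$truth$true_recruitment_region
  idx <- which(region, arr.ind = TRUE)
  d <- oracle_segment_distance(idx[, 2], idx[, 1],
                               cfg$ablation_roi[1, ], cfg$ablation_roi[2, ])
  expect_lte(max(d), cfg$recruitment_radius / cfg$pixel_size + 1e-6)
  # recruitment actually raises the reporter toward (1 + A) x baseline
  post <- sim$timelapse$reporter[, , 20]
  base <- sim$timelapse$reporter[, , 1]
  core <- region & (sim$timelapse$reporter[, , 20] / base > 1)
  expect_gt(sum(core), 0)
  expect_lte(max(post / base), 1 + cfg$recruitment_amplitude + 1e-9)
})

test_that("annular recruitment stays between the inner and outer radius", {
  cfg <- quick_config(recruitment_radius = 6, recruitment_inner_radius = 3.5)
  sim <- simulate_timelapse(cfg)
  idx <- which(sim$truth$true_recruitment_region, arr.ind = TRUE)
  d <- oracle_segment_distance(idx[, 2], idx[, 1],
                               cfg$ablation_roi[1, ], cfg$ablation_roi[2, ])
  d_um <- d * cfg$pixel_size
  expect_gte(min(d_um), cfg$recruitment_inner_radius - 1e-6)
  expect_lte(max(d_um), cfg$recruitment_radius + 1e-6)
})

test_that("actin is depleted inside the ablation zone after ablation", {
  cfg <- quick_config(actin_depletion_fraction = 0.8)
  sim <- simulate_timelapse(cfg)
  zone <- sim$truth$true_ablation_zone
  pre <- sim$timelapse$actin[, , 1]
  post <- sim$timelapse$actin[, , 6] # first post-ablation frame
  expect_lt(min(post[zone] / pre[zone]), 0.25)
  expect_equal(post[!zone], pre[!zone], tolerance = 1e-9)
})

test_that("line scans: flat reporter at fold 1, exact fold geometry", {
  ls1 <- simulate_linescan(fold = 1.0, noise_sd = 0)
  expect_equal(diff(range(ls1$profile$reporter)), 0)
  expect_error(simulate_linescan(fold = -1), "fold")
  ls2 <- simulate_linescan(fold = 2.0, noise_sd = 0)
  p <- ls2$profile
  expect_true(!is.unsorted(p$position_um, strictly = TRUE))
  # phalloidin minimum at the scan centre; both channels symmetric
  expect_equal(which.min(p$phalloidin), ls2$truth$centre_index)
  expect_equal(p$phalloidin, rev(p$phalloidin), tolerance = 1e-12)
  expect_equal(p$reporter, rev(p$reporter), tolerance = 1e-12)
  expect_equal(max(p$reporter) / min(p$reporter), 2.0, tolerance = 1e-12)
  # seeded determinism of the noisy profile
  a <- simulate_linescan(1.4, noise_sd = 2, seed = 3L)
  b <- simulate_linescan(1.4, noise_sd = 2, seed = 3L)
  expect_identical(a$profile, b$profile)
})

test_that("count study: degenerate rates and determinism", {
  z <- simulate_count_study(3, 15, gap_rate = 0, death_rate = 0, seed = 1L)
  expect_true(all(z$table$cells_with_gaps == 0))
  expect_true(all(z$table$cells_dead == 0))
  o <- simulate_count_study(3, 15, gap_rate = 1, death_rate = 0.5, seed = 1L)
  expect_true(all(o$table$cells_with_gaps == o$table$cells_total))
  two <- simulate_count_study(4, 10, 0.1, 0.1, seed = 2L, n_organs = 3L)
  expect_equal(nrow(two$table), 12)
  expect_equal(length(unique(two$table$organ_id)), 3)
  expect_identical(
    simulate_count_study(4, 10, 0.1, 0.1, seed = 2L, n_organs = 3L)$table,
    two$table
  )
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_timelapse(quick_config(gaussian_sd = 0.02)))
  expect_identical(.Random.seed, before)
})
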