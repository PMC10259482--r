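test_that("crop window geometry and missing-value bands", {
  expect_error(crop_window(c(50, 50), size = 120L), "odd")
  stack <- array(test_scene(200, seed = 31), c(200, 200, 2))
  # interior crop: no missing pixels
  w <- crop_window(c(100, 100), size = 121L)
  inner <- crop_stack(stack, w)
  expect_equal(dim(inner), c(121, 121, 2))
  expect_false(anyNA(inner))
  expect_equal(inner[61, 61, 1], stack[100, 100, 1])
  # centre 50 px from the left edge: left band of width 10 missing
  wl <- crop_stack(stack, crop_window(c(51, 100), size = 121L))
  expect_true(all(is.na(wl[, 1:10, ])))
  expect_false(anyNA(wl[, 11:121, ]))
  # constant frame -> constant crop
  const <- crop_stack(array(3, c(200, 200, 1)), w)
  expect_true(all(const == 3))
  expect_error(crop_stack(stack, crop_window(c(1000, 1000), size = 121L)),
               "outside")
})

test_that("reference image: mean of pre-ablation frames", {
  stack <- array(0, c(8, 8, 4))
  stack[, , 1] <- 2
  stack[, , 2] <- 4
  stack[, , 3:4] <- 9
  ref <- make_reference(stack, ablation_frame = 3L)
  expect_equal(unclass(ref), matrix(3, 8, 8), ignore_attr = TRUE)
  expect_equal(attr(ref, "n_frames_used"), 2L)
  expect_error(make_reference(stack, 2L), "insufficient_baseline")
  # variance of the mean: reference pixel variance ~ frame variance / n
  set.seed(32)
  noisy <- array(rnorm(64 * 64 * 15, 100, 5), c(64, 64, 15))
  refn <- make_reference(noisy, 16L)
  expect_equal(var(as.vector(refn)), 25 / 15, tolerance = 0.15)
})

test_that("relative difference against the reference", {
  ref <- matrix(50, 10, 10)
  attr(ref, "n_frames_used") <- 2L
  stack <- array(0, c(10, 10, 2))
  stack[, , 1] <- 50
  stack[, , 2] <- 100
  rd <- relative_difference(stack, ref)
  expect_equal(rd[, , 1], matrix(0, 10, 10))
  expect_equal(rd[, , 2], matrix(1, 10, 10))
  # divisor floor: tiny reference pixels become missing
  ref2 <- matrix(50, 10, 10)
  ref2[1, 1:7] <- 1e-12
  rd2 <- relative_difference(array(1.5 * ref2, c(10, 10, 1)), ref2)
  expect_equal(sum(is.na(rd2)), 7)
  expect_equal(rd2[, , 1][!is.na(rd2[, , 1])], rep(0.5, 93))
})

test_that("top-fraction mask: cardinality, ties, planted values", {
  m <- matrix(0, 10, 10)
  mask <- top_fraction_mask(m, 0.05)
  expect_equal(attr(mask, "k"), 5L)
  expect_equal(sum(mask), 5)
  # tie-break: first 5 pixels in row-major order = row 1, columns 1:5
  expect_true(all(mask[1, 1:5]))
  # planted values are found exactly
  set.seed(33)
  planted <- sample(100, 5)
  m2 <- matrix(0, 10, 10)
  m2[planted] <- 10
  expect_equal(which(top_fraction_mask(m2, 0.05)), sort(planted))
  # k follows the number of VALID pixels
  m3 <- matrix(rnorm(100), 10, 10)
  m3[sample(100, 30)] <- NA
  mask3 <- top_fraction_mask(m3, 0.05)
  expect_equal(attr(mask3, "k"), round(0.05 * 70))
  expect_false(any(mask3 & is.na(m3)))
  expect_error(top_fraction_mask(matrix(c(1, rep(NA, 24)), 5, 5)),
               "fewer than 20")
})

test_that("trace extraction: baseline zero, fold column, sign of depletion", {
  rd0 <- array(0, c(10, 10, 6))
  masks <- mask_series(rd0, 0.05)
  expect_equal(attr(masks, "k"), rep(5L, 6))
  tr <- extract_trace(rd0, rd0, masks, time_s = seq(-4, 6, by = 2))
  expect_equal(tr$rel_diff_reporter, rep(0, 6))
  expect_equal(tr$fold_reporter - tr$rel_diff_reporter, rep(1, 6),
               tolerance = 1e-12)
  # empty mask raises
  bad <- masks
  bad[, , 3] <- FALSE
  expect_error(extract_trace(rd0, rd0, bad, seq(-4, 6, by = 2)),
               "empty mask")
  # actin depletion read through the reporter mask dips negative
  sim <- simulate_timelapse(quick_config())
  run <- quantify_recruitment(sim$timelapse)
  post <- run$trace$time_s > 10
  expect_lt(mean(run$trace$rel_diff_actin[post]), -0.05)
  expect_gt(trace_plateau(run$trace, "reporter"), 0.1)
})

test_that("trace aggregation across videos", {
  t1 <- data.frame(time_s = c(0, 2, 4), rel_diff_reporter = c(0.4, 0.4, 0.4),
                   rel_diff_actin = 0, fold_reporter = 1.4, fold_actin = 1,
                   video_id = "a")
  t2 <- t1
  t2$rel_diff_reporter <- c(0.6, 0.6, 0.6)
  t2$video_id <- "b"
  class(t1) <- class(t2) <- c("recruitment_trace", "data.frame")
  ens <- aggregate_traces(list(t1, t2))
  expect_equal(ens$mean_reporter, rep(0.5, 3))
  expect_equal(ens$sd_reporter, rep(sd(c(0.4, 0.6)), 3), tolerance = 1e-12)
  expect_equal(ens$n_videos, rep(2, 3))
  one <- aggregate_traces(list(t1))
  expect_equal(one$mean_reporter, t1$rel_diff_reporter)
  expect_equal(one$sd_reporter, rep(0, 3))
  t3 <- t1
  t3$time_s <- c(0, 3.5, 7)
  expect_error(aggregate_traces(list(t1, t3)), "incompatible")
})

test_that("spatial probability: counting, conservation, classification", {
  masks <- array(FALSE, c(21, 21, 10))
  masks[5, 5, 1:3] <- TRUE
  masks[11, 11, ] <- TRUE
  ms <- structure(masks, fraction = 0.05, k = rep(1L, 10),
                  class = "mask_series")
  map <- spatial_probability(list(ms), ablation_frames = 1L)
  expect_equal(map$prob[5, 5], 0.3)
  expect_equal(map$prob[11, 11], 1.0)
  expect_true(all(map$prob >= 0 & map$prob <= 1))
  # identical masks -> indicator map
  same <- array(FALSE, c(21, 21, 4))
  same[3, 7, ] <- TRUE
  same[9, 2, ] <- TRUE
  ms2 <- structure(same, fraction = 0.05, k = rep(2L, 4),
                   class = "mask_series")
  map2 <- spatial_probability(list(ms2), ablation_frames = 1L)
  expect_true(all(map2$prob %in% c(0, 1)))
  expect_equal(sum(map2$prob), 2)
  # probability mass conservation: sum(prob) = mean mask cardinality
  sim <- simulate_timelapse(quick_config(gaussian_sd = 0.02))
  run <- quantify_recruitment(sim$timelapse)
  m <- spatial_probability(list(run$masks), ablation_frames = 6L,
                           pixel_size_um = 0.173)
  expect_equal(sum(m$prob), mean(attr(run$masks, "k")), tolerance = 1e-9)
})

test_that("strain-region fraction and classification", {
  uniform <- structure(list(prob = matrix(0.05, 121, 121), n_timepoints = 10L,
                            strain_radius_um = 3.5, pixel_size_um = 0.173,
                            ablation_segment = NULL),
                       class = "spatial_probability_map")
  s <- strain_region_fraction(uniform)
  expect_equal(s$inside_fraction, s$area_fraction, tolerance = 1e-12)
  expect_equal(s$classification, "random")
  centre <- uniform
  centre$prob <- matrix(0, 121, 121)
  centre$prob[61, 61] <- 1
  sc <- strain_region_fraction(centre)
  expect_equal(sc$inside_fraction, 1.0)
  expect_equal(sc$classification, "inside_enriched")
  expect_error(strain_region_fraction(uniform, radius_um = 0), "degenerate")
})

test_that("end-to-end recovery and the value of registration", {
  cfg <- quick_config(
    image_size = c(128L, 128L), crop_size = 81L,
    n_pre_frames = 6L, n_post_frames = 24L,
    drift_per_frame = c(0.4, 0), bleach_tau = 120,
    gaussian_sd = 0.01, recruitment_amplitude = 0.5,
    recruitment_halftime = 6, seed = 9L
  )
  sim <- simulate_timelapse(cfg)
  run <- quantify_recruitment(sim$timelapse)
  plateau <- trace_plateau(run$trace, "reporter")
  expect_lt(abs(plateau - 0.5) / 0.5, 0.15)
  # recovered shifts track the injected drift
  err <- cbind(run$shifts$dy_px, run$shifts$dx_px) - sim$truth$true_shifts
  expect_lt(sqrt(mean(err^2)), 0.1)

  # same stack analysed WITHOUT registration: recovery degrades
  tl <- sim$timelapse
  pre <- 1:6
  ff <- estimate_flatfield(tl$reporter[, , pre], 10, 0.173)
  rep_c <- apply_flatfield(tl$reporter, ff)
  model <- fit_bleach(rep_c, tl$meta$frame_times_s)
  rep_c <- correct_bleach(rep_c, model, tl$meta$frame_times_s)
  w <- crop_window(colMeans(tl$meta$ablation_roi), 81L, 0.173)
  crop <- crop_stack(rep_c, w)
  rd <- relative_difference(crop, make_reference(crop, 7L))
  tr <- extract_trace(rd, rd, mask_series(rd, 0.05),
                      tl$meta$frame_times_s - tl$meta$frame_times_s[7])
  plateau_noreg <- trace_plateau(tr, "reporter")
  expect_gt(abs(plateau_noreg - 0.5), abs(plateau - 0.5))
})
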