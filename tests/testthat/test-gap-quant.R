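make_profile <- function(phalloidin, reporter = rep(100, length(phalloidin))) {
  n <- length(phalloidin)
  data.frame(position_um = seq(0, 4, length.out = n),
             phalloidin = phalloidin, reporter = reporter)
}

test_that("line-scan validation names the offending column", {
  p <- make_profile(rep(100, 20))
  expect_error(validate_linescan(p[, c("position_um", "phalloidin")]),
               "reporter")
  expect_error(validate_linescan(p[1:10, ]), ">= 15")
  bad <- p
  bad$position_um[5] <- bad$position_um[4]
  expect_error(validate_linescan(bad), "strictly increasing")
})

test_that("gap centre: minimum, tie-break, flat warning", {
  v <- c(seq(100, 20, length.out = 20), seq(24, 100, length.out = 21))
  p <- make_profile(v)
  expect_equal(find_gap_center(p, smooth = 1L), 20)
  # two equal minima at 18 and 22: lower index wins
  v2 <- rep(100, 41)
  v2[c(18, 22)] <- 10
  expect_equal(find_gap_center(make_profile(v2), smooth = 1L), 18)
  expect_warning(ct <- find_gap_center(make_profile(rep(7, 41)), smooth = 1L),
                 "flat window")
  expect_equal(ct, 1)
  # search window restricts the minimum
  expect_equal(find_gap_center(p, window = c(25, 41), smooth = 1L), 25)
})

test_that("gap edges: analytic 90% crossing, symmetry, open gap", {
  ls <- simulate_linescan(fold = 2, gap_depth = 0.6, noise_sd = 0, n = 81L)
  p <- ls$profile
  centre <- find_gap_center(p)
  expect_equal(centre, ls$truth$centre_index)
  edges <- find_gap_edges(p, centre)
  expect_equal(unname(diff(c(edges[1], centre))),
               unname(diff(c(centre, edges[2]))))
  # closed-form 90%-of-plateau crossing of the Gaussian dip:
  # 1 - depth * exp(-u^2 / (2 sigma^2)) = 0.9  =>  u* = sigma
  # * sqrt(2 log(10 depth)); edges within +/- 1 sample of the analytic u*
  du <- p$position_um[2] - p$position_um[1]
  u_star <- ls$truth$gap_sigma_um * sqrt(2 * log(10 * ls$truth$gap_depth))
  analytic <- u_star / du
  expect_lte(abs((centre - edges[1]) - analytic), 1 + 2) # smoothing half-width 2
  expect_gte(centre - edges[1], analytic - 1)
  # dip running off the scan: no measurable edge
  wide <- simulate_linescan(fold = 1, gap_depth = 0.9, noise_sd = 0,
                            n = 41L, gap_sigma_um = 1.5)$profile
  expect_error(find_gap_edges(wide, find_gap_center(wide)), "open_gap")
})

test_that("enrichment ratio: exact constructions and invariances", {
  flat <- make_profile(c(rep(100, 15), 60, 30, 60, rep(100, 15)))
  call_flat <- enrichment_ratio(flat, smooth = 1L)
  expect_s3_class(call_flat, "gap_call")
  expect_equal(call_flat$enrichment_ratio, 1.0)
  # reporter 200 at the centre, 100 at both edges -> 2.0
  p <- flat
  centre <- find_gap_center(p, smooth = 1L)
  edges <- find_gap_edges(p, centre, smooth = 1L)
  p$reporter[centre] <- 200
  call2 <- enrichment_ratio(p, center = centre, edges = edges, smooth = 1L)
  expect_equal(call2$enrichment_ratio, 2.0)
  expect_true(call2$edge_index_left < call2$center_index)
  expect_true(call2$center_index < call2$edge_index_right)
  # generator profiles: fold recovered exactly in the noise-free case
  for (fold in c(1.0, 2.0)) {
    ls <- simulate_linescan(fold = fold, noise_sd = 0)
    expect_equal(enrichment_ratio(ls$profile)$enrichment_ratio, fold,
                 tolerance = 1e-9)
  }
  # scaling the reporter leaves the ratio unchanged
  ls <- simulate_linescan(fold = 1.4, noise_sd = 1, seed = 4L)
  r1 <- enrichment_ratio(ls$profile)
  scaled <- ls$profile
  scaled$reporter <- scaled$reporter * 37
  r2 <- enrichment_ratio(scaled)
  expect_equal(r2$enrichment_ratio, r1$enrichment_ratio, tolerance = 1e-12)
  # scaling the phalloidin never moves the located indices
  scaled$phalloidin <- scaled$phalloidin * 0.2
  r3 <- enrichment_ratio(scaled)
  expect_equal(r3$center_index, r1$center_index)
  expect_equal(r3$edge_index_left, r1$edge_index_left)
  expect_equal(r3$edge_index_right, r1$edge_index_right)
})

test_that("noisy gap centre lands within one sample in >= 95% of runs", {
  hits <- vapply(1:500, function(s) {
    ls <- simulate_linescan(fold = 1.4, noise_sd = 2, seed = s)
    abs(find_gap_center(ls$profile) - ls$truth$centre_index) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("per-organ enrichment aggregation", {
  calls <- list(
    structure(list(enrichment_ratio = 2.0, organ_id = "u1"),
              class = "gap_call"),
    structure(list(enrichment_ratio = 1.0, organ_id = "u1"),
              class = "gap_call"),
    structure(list(enrichment_ratio = 1.5, organ_id = "u2"),
              class = "gap_call")
  )
  agg <- aggregate_enrichment(calls)
  u1 <- agg[agg$organ_id == "u1", ]
  expect_equal(u1$mean_ratio, 1.5)
  expect_equal(u1$n, 2)
  expect_equal(u1$se, sd(c(2, 1)) / sqrt(2))
  expect_true(is.na(agg$se[agg$organ_id == "u2"]))
  # two-group study: group means recovered within 5% at 2% noise
  group_mean <- function(fold, seed0) {
    ratios <- vapply(1:40, function(i) {
      ls <- simulate_linescan(fold = fold, noise_sd = 2, seed = seed0 + i)
      enrichment_ratio(ls$profile)$enrichment_ratio
    }, numeric(1))
    mean(ratios)
  }
  expect_lt(abs(group_mean(2.0, 1000) - 2.0) / 2.0, 0.05)
  expect_lt(abs(group_mean(1.3, 2000) - 1.3) / 1.3, 0.05)
})

test_that("count-table statistics: pooled per-organ percentages", {
  toy <- data.frame(
    organ_id = "cochlea1", image_id = c("im1", "im2", "im3"),
    cells_total = c(15L, 15L, 15L),
    cells_with_gaps = c(2L, 0L, 1L),
    cells_dead = c(9L, 0L, 0L),
    stereocilia_total = c(300L, 300L, 300L)
  )
  gf <- gap_frequency(toy)
  expect_equal(gf$percent_with_gaps, 100 * 3 / 45)
  expect_equal(gf$cells_total, 45)
  dc <- dead_cell_percent(toy)
  expect_equal(dc$percent_dead, 20)
  sm <- stereocilia_mean(toy)
  expect_equal(sm$mean_stereocilia, 20.0)
  # zero numerator
  toy0 <- toy
  toy0$cells_with_gaps <- 0L
  expect_equal(gap_frequency(toy0)$percent_with_gaps, 0)
  # single cell
  one <- data.frame(organ_id = "u", image_id = "i", cells_total = 1L,
                    cells_with_gaps = 0L, cells_dead = 0L,
                    stereocilia_total = 17L)
  expect_equal(stereocilia_mean(one)$mean_stereocilia, 17.0)
  # monotone in the numerator
  more <- toy
  more$cells_with_gaps <- c(3L, 0L, 1L)
  expect_gt(gap_frequency(more)$percent_with_gaps, gf$percent_with_gaps)
})

test_that("count-table validation names columns and checks invariants", {
  toy <- data.frame(organ_id = "a", image_id = "i", cells_total = 10L,
                    cells_with_gaps = 2L, cells_dead = 1L,
                    stereocilia_total = 100L)
  expect_error(validate_count_table(toy[, -4]), "cells_with_gaps")
  bad <- toy
  bad$cells_with_gaps <- 12L
  expect_error(validate_count_table(bad), "exceeds cells_total")
  neg <- toy
  neg$cells_dead <- -1L
  expect_error(validate_count_table(neg), "negative")
})
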