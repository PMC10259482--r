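# Centred moving average preserving length; edge samples use the partial
# window. Window must be odd.
smooth_profile <- function(x, window = 5L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

validate_linescan <- function(profile) {
  req <- c("position_um", "phalloidin", "reporter")
  miss <- setdiff(req, names(profile))
  if (length(miss)) {
    stop("line-scan profile is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(profile) < 15) stop("line-scan profile must have >= 15 samples")
  if (is.unsorted(profile$position_um, strictly = TRUE)) {
    stop("line-scan positions must be strictly increasing")
  }
  invisible(profile)
}

#' Locate the gap centre on a line scan
#'
#' The gap centre is the sample with the lowest phalloidin fluorescence
#' within the search window, after smoothing with a centred moving average.
#' Ties are broken toward the lower index.
#'
#' @param profile data frame with columns `position_um`, `phalloidin`,
#'   `reporter` (see [simulate_linescan()]).
#' @param window integer index range `c(first, last)` to search; default the
#'   whole scan.
#' @param smooth moving-average window in samples (odd; default 5).
#' @return integer index of the gap centre.
#' @export
find_gap_center <- function(profile, window = NULL, smooth = 5L) {
  validate_linescan(profile)
  n <- nrow(profile)
  if (is.null(window)) window <- c(1L, n)
  stopifnot(window[1] >= 1, window[2] <= n, diff(window) + 1 >= 5)
  s <- smooth_profile(profile$phalloidin, smooth)
  idx <- window[1]:window[2]
  sv <- s[idx]
  if (max(sv) - min(sv) == 0) {
    warning("find_gap_center: flat window; tie-break toward lower index")
  }
  idx[which.min(sv)]
}

#' Locate the gap edges on a line scan
#'
#' Walking outward from the gap centre on each side, the edge is the first
#' sample where the smoothed phalloidin signal recovers to at least
#' `edge_threshold` (default 90%) of that side's flanking plateau, the
#' plateau being the median of the outer quartile of samples on that side.
#' This operationalizes "where the signal begins to decrease" robustly; a
#' literal derivative-sign criterion is unstable under noise.
#'
#' If the first threshold crossing falls inside the outer-quartile flank
#' itself, the dip extends into the region used to estimate the plateau --
#' the gap runs off the scan and has no measurable edge on that side -- and
#' the error `"open_gap"` is raised.
#'
#' @inheritParams find_gap_center
#' @param center centre index from [find_gap_center()].
#' @param edge_threshold fraction of the flanking plateau (default 0.9).
#' @return integer vector `c(left, right)` of edge indices.
#' @export
find_gap_edges <- function(profile, center, smooth = 5L, edge_threshold = 0.9) {
  validate_linescan(profile)
  n <- nrow(profile)
  stopifnot(center >= 2, center <= n - 1, edge_threshold > 0,
            edge_threshold <= 1)
  s <- smooth_profile(profile$phalloidin, smooth)

  side_edge <- function(indices_outward, flank_idx) {
    if (length(flank_idx) < 1) stop("open_gap")
    plateau <- stats::median(s[flank_idx])
    hit <- indices_outward[s[indices_outward] >= edge_threshold * plateau]
    if (length(hit) == 0 || hit[1] %in% flank_idx) stop("open_gap")
    hit[1]
  }
  n_left <- center - 1L
  n_right <- n - center
  left_flank <- seq_len(max(1L, ceiling(0.25 * n_left)))
  right_flank <- n - seq_len(max(1L, ceiling(0.25 * n_right))) + 1L
  left <- side_edge((center - 1L):1L, left_flank)
  right <- side_edge((center + 1L):n, right_flank)
  c(left = left, right = right)
}

#' Gap enrichment ratio of a reporter on a line scan
#'
#' The reporter intensity at the gap centre divided by the reporter intensity
#' at the gap edge (mean of the two edges, for symmetry and lower variance).
#' Reporter values are read from the smoothed reporter signal at the located
#' indices. Centre and edges are located automatically from the phalloidin
#' channel when not supplied.
#'
#' @inheritParams find_gap_edges
#' @param center optional centre index; located by [find_gap_center()] if
#'   `NULL`.
#' @param edges optional `c(left, right)` edge indices; located by
#'   [find_gap_edges()] if `NULL`.
#' @param window search window passed to [find_gap_center()].
#' @return list of class `gap_call`: `center_index`, `edge_index_left`,
#'   `edge_index_right`, `center_reporter`, `edge_reporter`,
#'   `enrichment_ratio`, `organ_id`, `cell_id`.
#' @export
enrichment_ratio <- function(profile, center = NULL, edges = NULL,
                             window = NULL, smooth = 5L,
                             edge_threshold = 0.9) {
  validate_linescan(profile)
  if (is.null(center)) center <- find_gap_center(profile, window, smooth)
  if (is.null(edges)) {
    edges <- find_gap_edges(profile, center, smooth, edge_threshold)
  }
  stopifnot(edges[1] < center, center < edges[2])
  sr <- smooth_profile(profile$reporter, smooth)
  edge_val <- mean(sr[edges])
  if (edge_val <= 0) stop("enrichment_ratio: non-positive edge intensity")
  structure(list(
    center_index = as.integer(center),
    edge_index_left = as.integer(edges[1]),
    edge_index_right = as.integer(edges[2]),
    center_reporter = sr[center],
    edge_reporter = edge_val,
    enrichment_ratio = sr[center] / edge_val,
    organ_id = if ("organ_id" %in% names(profile)) profile$organ_id[1] else NA,
    cell_id = if ("cell_id" %in% names(profile)) profile$cell_id[1] else NA
  ), class = "gap_call")
}

#' Per-organ mean gap enrichment ratio
#'
#' @param calls list of [enrichment_ratio()] results, or a data frame with
#'   columns `organ_id` and `enrichment_ratio`.
#' @return data frame: `organ_id`, `mean_ratio`, `n`, `se` (`NA` for a single
#'   call).
#' @export
aggregate_enrichment <- function(calls) {
  if (is.data.frame(calls)) {
    df <- calls[, c("organ_id", "enrichment_ratio")]
  } else {
    stopifnot(length(calls) >= 1)
    df <- data.frame(
      organ_id = vapply(calls, function(cl) as.character(cl$organ_id),
                        character(1)),
      enrichment_ratio = vapply(calls, function(cl) cl$enrichment_ratio,
                                numeric(1))
    )
  }
  if (nrow(df) == 0) stop("aggregate_enrichment: empty group")
  agg <- do.call(rbind, lapply(split(df, df$organ_id), function(g) {
    n <- nrow(g)
    data.frame(
      organ_id = g$organ_id[1],
      mean_ratio = mean(g$enrichment_ratio),
      n = n,
      se = if (n > 1) stats::sd(g$enrichment_ratio) / sqrt(n) else NA_real_
    )
  }))
  rownames(agg) <- NULL
  agg
}

validate_count_table <- function(table) {
  req <- c("organ_id", "image_id", "cells_total", "cells_with_gaps",
           "cells_dead", "stereocilia_total")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  }
  counts <- table[, c("cells_total", "cells_with_gaps", "cells_dead",
                      "stereocilia_total")]
  if (any(counts < 0)) stop("count table: negative counts")
  if (any(table$cells_with_gaps > table$cells_total)) {
    stop("count table: cells_with_gaps exceeds cells_total")
  }
  if (any(table$cells_dead > table$cells_total)) {
    stop("count table: cells_dead exceeds cells_total")
  }
  invisible(table)
}

per_organ_percent <- function(table, numerator_col) {
  validate_count_table(table)
  out <- do.call(rbind, lapply(split(table, table$organ_id), function(g) {
    total <- sum(g$cells_total)
    if (total == 0) stop("count table: zero total cells for organ ",
                         g$organ_id[1])
    data.frame(
      organ_id = g$organ_id[1],
      cells_total = total,
      numerator = sum(g[[numerator_col]]),
      percent = 100 * sum(g[[numerator_col]]) / total
    )
  }))
  rownames(out) <- NULL
  out
}

#' Per-organ percentage of cells with gaps
#'
#' Counts are pooled over an organ's images (sum of numerators over sum of
#' cells), not averaged per image, because images carry unequal cell counts.
#'
#' @param table count table (see [simulate_count_study()]): columns
#'   `organ_id`, `image_id`, `cells_total`, `cells_with_gaps`, `cells_dead`,
#'   `stereocilia_total`.
#' @return data frame: `organ_id`, `cells_total`, `cells_with_gaps`,
#'   `percent_with_gaps`.
#' @export
gap_frequency <- function(table) {
  out <- per_organ_percent(table, "cells_with_gaps")
  names(out)[3:4] <- c("cells_with_gaps", "percent_with_gaps")
  out
}

#' Per-organ percentage of dead cells
#'
#' @inheritParams gap_frequency
#' @return data frame: `organ_id`, `cells_total`, `cells_dead`,
#'   `percent_dead`.
#' @export
dead_cell_percent <- function(table) {
  out <- per_organ_percent(table, "cells_dead")
  names(out)[3:4] <- c("cells_dead", "percent_dead")
  out
}

#' Per-organ mean stereocilia per cell
#'
#' @inheritParams gap_frequency
#' @return data frame: `organ_id`, `cells_total`, `stereocilia_total`,
#'   `mean_stereocilia`.
#' @export
stereocilia_mean <- function(table) {
  validate_count_table(table)
  out <- do.call(rbind, lapply(split(table, table$organ_id), function(g) {
    total <- sum(g$cells_total)
    if (total == 0) stop("count table: zero total cells for organ ",
                         g$organ_id[1])
    data.frame(
      organ_id = g$organ_id[1],
      cells_total = total,
      stereocilia_total = sum(g$stereocilia_total),
      mean_stereocilia = sum(g$stereocilia_total) / total
    )
  }))
  rownames(out) <- NULL
  out
}
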