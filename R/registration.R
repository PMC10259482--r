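#' Sub-pixel translation estimate by phase cross-correlation
#'
#' Estimates the rigid translation between two images of identical size using
#' normalized cross-power (phase) correlation, refined to `1/upsample_factor`
#' pixel by an upsampled discrete Fourier transform evaluated by matrix
#' multiplication around the integer-pixel peak.
#'
#' Sign convention (fixed): the returned shift maps reference coordinates onto
#' image coordinates, i.e. `image[y, x] ~= reference[y - dy, x - dx]`. A
#' feature at `(y0, x0)` in the reference appears at `(y0 + dy, x0 + dx)` in
#' the image. To register the image back onto the reference, translate it by
#' `(-dy, -dx)`.
#'
#' @param image numeric matrix, the moving image.
#' @param reference numeric matrix of the same dimensions, the fixed image.
#' @param upsample_factor integer >= 1; the estimate is refined to
#'   `1/upsample_factor` pixel. 1 gives whole-pixel resolution.
#' @return named numeric vector `c(dy, dx)` in pixels.
#' @examples
#' ref <- matrix(rnorm(64 * 64), 64, 64)
#' img <- ref[c(62:64, 1:61), ] # circular shift by +3 rows
#' estimate_shift(img, ref, upsample_factor = 1)
#' @export
estimate_shift <- function(image, reference, upsample_factor = 100L) {
  stopifnot(is.matrix(image), is.matrix(reference))
  if (!all(dim(image) == dim(reference))) {
    stop("estimate_shift: image and reference dimensions differ")
  }
  upsample_factor <- as.integer(upsample_factor)
  stopifnot(upsample_factor >= 1L)
  if (anyNA(image) || anyNA(reference)) {
    stop("estimate_shift: input contains missing values")
  }
  if (stats::sd(image) == 0 || stats::sd(reference) == 0) {
    stop("no_signal")
  }
  nr <- nrow(image)
  nc <- ncol(image)

  f_img <- fft2(image)
  f_ref <- fft2(reference)
  cross <- f_img * Conj(f_ref)
  mag <- Mod(cross)
  tol <- max(mag) * 1e-12
  norm_cross <- ifelse(mag > tol, cross / mag, 0 + 0i)
  # For a real image the phase at the Nyquist frequency is sign-ambiguous
  # under sub-pixel translation; those bins carry no usable phase and would
  # bias the upsampled peak, so they are excluded from the correlation.
  if (nr %% 2 == 0) norm_cross[nr / 2 + 1, ] <- 0 + 0i
  if (nc %% 2 == 0) norm_cross[, nc / 2 + 1] <- 0 + 0i

  cc <- ifft2(norm_cross)
  peak <- which.max(Mod(cc))
  iy <- (peak - 1L) %% nr
  ix <- (peak - 1L) %/% nr
  if (iy > nr %/% 2) iy <- iy - nr
  if (ix > nc %/% 2) ix <- ix - nc
  shift <- c(dy = as.numeric(iy), dx = as.numeric(ix))

  if (upsample_factor > 1L) {
    shift <- round(shift * upsample_factor) / upsample_factor
    region <- ceiling(upsample_factor * 1.5)
    dftshift <- region %/% 2
    cc_up <- dft_upsample(
      norm_cross, region, region, upsample_factor,
      roff = dftshift - shift["dy"] * upsample_factor,
      coff = dftshift - shift["dx"] * upsample_factor
    )
    pk <- which.max(Mod(cc_up))
    py <- (pk - 1L) %% region
    px <- (pk - 1L) %/% region
    shift <- shift + c(py - dftshift, px - dftshift) / upsample_factor
    names(shift) <- c("dy", "dx")
  }
  shift
}

#' Register a time-lapse stack to a fixed reference
#'
#' Estimates per-frame translations of a (corrected) stack against a fixed
#' reference image by [estimate_shift()] and aligns every frame by applying
#' the negated shift via Fourier translation. The default reference is the
#' temporal mean of the pre-ablation frames, which is stable and has high
#' signal-to-noise; a fixed reference avoids the drift accumulation of
#' frame-to-frame chaining.
#'
#' The shift series is re-anchored to `anchor_frame` (default the first
#' frame): the estimate for the anchor is subtracted from all frames, so the
#' reported shifts are motion relative to the anchor frame's coordinate
#' system. This cancels the constant offset that a motion-blurred mean
#' reference would otherwise impose and keeps ablation-ROI metadata (defined
#' in first-frame coordinates) valid after registration.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param ablation_frame 1-based index of the first post-ablation frame; the
#'   reference is the mean of frames `1:(ablation_frame - 1)`. Ignored when
#'   `reference` is supplied.
#' @param reference optional explicit reference image.
#' @param upsample_factor passed to [estimate_shift()]; default 100
#'   (0.01 px resolution).
#' @param anchor_frame frame whose estimated shift defines zero.
#' @return list with `stack` (registered array, border pixels exposed by the
#'   translation set to `NA`), and `shifts`, a `shift_series` data frame with
#'   columns `frame`, `dy_px`, `dx_px` plus attributes `reference_descriptor`
#'   and `upsample_factor`.
#' @export
register_series <- function(stack, ablation_frame = NULL, reference = NULL,
                            upsample_factor = 100L, anchor_frame = 1L) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nt <- dim(stack)[3]
  if (is.null(reference)) {
    if (is.null(ablation_frame)) {
      stop("register_series: supply ablation_frame or an explicit reference")
    }
    stopifnot(ablation_frame >= 2, ablation_frame <= nt + 1)
    # Two-pass reference: align the pre-ablation frames to the anchor frame
    # first, then average them. Averaging unaligned frames would blur the
    # reference and, worse, leave each pre-ablation frame's own noise inside
    # it, whose whitened zero-lag self-correlation biases that frame's
    # estimate toward zero.
    pre_idx <- seq_len(ablation_frame - 1)
    stopifnot(anchor_frame %in% pre_idx)
    pass1 <- t(vapply(
      pre_idx,
      function(i) estimate_shift(stack[, , i], stack[, , anchor_frame],
                                 upsample_factor),
      numeric(2)
    ))
    aligned_pre <- apply_shifts(stack[, , pre_idx, drop = FALSE],
                                shift_series(pass1[, 1], pass1[, 2]))
    reference <- frame_mean_image(aligned_pre)
    if (anyNA(reference)) {
      stop("register_series: pre-ablation drift leaves unobserved pixels")
    }
    descriptor <- sprintf("mean(frames 1:%d aligned to frame %d)",
                          ablation_frame - 1, anchor_frame)
  } else {
    descriptor <- "user-supplied reference"
  }
  raw <- t(vapply(
    seq_len(nt),
    function(i) estimate_shift(stack[, , i], reference, upsample_factor),
    numeric(2)
  ))
  raw <- sweep(raw, 2, raw[anchor_frame, ])
  shifts <- shift_series(raw[, 1], raw[, 2],
    reference_descriptor = descriptor,
    upsample_factor = upsample_factor
  )
  list(stack = apply_shifts(stack, shifts), shifts = shifts)
}

#' Construct a shift series
#'
#' @param dy_px,dx_px per-frame translations in pixels (sub-pixel allowed).
#' @param reference_descriptor description of the image the series is
#'   relative to.
#' @param upsample_factor registration precision used to estimate the series.
#' @return data frame of class `shift_series` with columns
#'   `frame`, `dy_px`, `dx_px`.
#' @export
shift_series <- function(dy_px, dx_px, reference_descriptor = "frame 1",
                         upsample_factor = 1L) {
  stopifnot(length(dy_px) == length(dx_px), all(is.finite(dy_px)),
            all(is.finite(dx_px)))
  out <- data.frame(
    frame = seq_along(dy_px),
    dy_px = as.numeric(dy_px),
    dx_px = as.numeric(dx_px)
  )
  attr(out, "reference_descriptor") <- reference_descriptor
  attr(out, "upsample_factor") <- as.integer(upsample_factor)
  class(out) <- c("shift_series", "data.frame")
  out
}

#' Apply a shift series to a stack
#'
#' Translates frame `i` by `(-dy_px[i], -dx_px[i])` (undoing the estimated
#' motion) via Fourier translation. Border bands exposed by each translation
#' (width `ceiling(|shift|)` on the side content moved away from, covering
#' the wrap-around of the periodic translation) are set to `NA` and are
#' excluded from all downstream statistics for that frame only. Used to
#' propagate shifts estimated on the reporter channel to the actin channel.
#'
#' @param stack 3-D numeric array `[row, col, frame]` without missing values.
#' @param shifts a `shift_series` with one row per frame.
#' @return registered stack with `NA` in exposed border bands.
#' @export
apply_shifts <- function(stack, shifts) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nt <- dim(stack)[3]
  if (nrow(shifts) != nt) {
    stop("apply_shifts: shift series length does not match frame count")
  }
  nr <- dim(stack)[1]
  nc <- dim(stack)[2]
  if (any(abs(shifts$dy_px) >= nr / 2) || any(abs(shifts$dx_px) >= nc / 2)) {
    stop("apply_shifts: shifts exceed half the frame size")
  }
  out <- stack
  for (i in seq_len(nt)) {
    ty <- -shifts$dy_px[i]
    tx <- -shifts$dx_px[i]
    if (ty == 0 && tx == 0) next
    frame <- stack[, , i]
    if (anyNA(frame)) stop("apply_shifts: frame contains missing values")
    frame <- fourier_shift(frame, ty, tx)
    by <- ceiling(abs(ty))
    bx <- ceiling(abs(tx))
    if (by > 0) {
      rows <- if (ty > 0) seq_len(by) else nr - seq_len(by) + 1L
      frame[rows, ] <- NA_real_
    }
    if (bx > 0) {
      cols <- if (tx > 0) seq_len(bx) else nc - seq_len(bx) + 1L
      frame[, cols] <- NA_real_
    }
    out[, , i] <- frame
  }
  out
}

# Temporal mean image of a stack, ignoring missing values.
frame_mean_image <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  rowMeans(stack, dims = 2, na.rm = TRUE)
}
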