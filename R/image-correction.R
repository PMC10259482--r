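#' Estimate a flat-field gain map from a stack
#'
#' Pseudo-flat-field estimation: the temporal mean image is blurred with a
#' large Gaussian (default 10 um) and rescaled to unit mean, giving a
#' strictly positive multiplicative gain map. Alternatively a measured
#' calibration image can be supplied, in which case it is normalized to unit
#' mean and returned unchanged otherwise.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param sigma_um blur scale in um.
#' @param pixel_size_um pixel size used to convert `sigma_um` to pixels.
#' @param calibration optional calibration image (matrix); overrides the
#'   pseudo-flat-field construction.
#' @return matrix of class `flatfield`: strictly positive, unit mean.
#' @export
estimate_flatfield <- function(stack, sigma_um = 10, pixel_size_um = 0.173,
                               calibration = NULL) {
  if (!is.null(calibration)) {
    stopifnot(is.matrix(calibration), all(is.finite(calibration)))
    if (any(calibration <= 0)) stop("calibration image must be positive")
    gain <- calibration / mean(calibration)
  } else {
    stopifnot(is.array(stack), length(dim(stack)) == 3, sigma_um > 0,
              pixel_size_um > 0)
    m <- frame_mean_image(stack)
    if (all(m == 0)) stop("degenerate_stack")
    gain <- gaussian_blur_fft(m, sigma_um / pixel_size_um)
    if (any(gain <= 0)) stop("degenerate_stack")
    gain <- gain / mean(gain)
  }
  structure(gain, class = c("flatfield", class(gain)))
}

#' Apply a flat-field correction
#'
#' Divides every frame pixel-wise by the unit-mean gain map.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param flatfield gain map from [estimate_flatfield()].
#' @return corrected stack.
#' @export
apply_flatfield <- function(stack, flatfield) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (!all(dim(stack)[1:2] == dim(flatfield))) {
    stop("apply_flatfield: shape mismatch")
  }
  sweep(stack, c(1, 2), unclass(flatfield), "/")
}

#' Fit a mono-exponential photobleaching model
#'
#' Fits `m(t) = amplitude * exp(-t / tau) + offset` by nonlinear least
#' squares (Levenberg-Marquardt) to the per-frame mean intensity computed
#' over pixels outside `exclude_region`. Excluding a dilation of the ablation
#' region keeps post-ablation recruitment and depletion from biasing the fit.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param times frame times in seconds; default `0, dt, ...` with `dt = 1`.
#' @param exclude_region optional logical matrix (static exclusion) or 3-D
#'   logical array with one page per frame (an exclusion region that tracks
#'   the drifting scene); `TRUE` pixels are excluded from the per-frame
#'   means. On drifting stacks a static exclusion lets scene structure slide
#'   in and out of the kept region and puts a spurious trend into the frame
#'   means, so the pipeline passes a per-frame region.
#' @return list of class `bleach_model`: `amplitude`, `tau`, `offset`,
#'   `fit_residual` (root mean squared residual of the frame means),
#'   `frame_means`, `times`.
#' @export
fit_bleach <- function(stack, times = NULL, exclude_region = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nt <- dim(stack)[3]
  if (nt < 5) stop("fit_bleach: need at least 5 frames")
  if (is.null(times)) times <- seq_len(nt) - 1
  stopifnot(length(times) == nt)
  keep_for <- frame_keep_fun(exclude_region, dim(stack), "fit_bleach")
  m <- vapply(seq_len(nt), function(i) {
    mean(stack[, , i][keep_for(i)], na.rm = TRUE)
  }, numeric(1))

  # log-linear initial guess
  off0 <- 0.5 * min(m)
  pos <- m - off0
  lf <- stats::lm(log(pmax(pos, 1e-12)) ~ times)
  tau0 <- -1 / stats::coef(lf)[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(times)) + 1
  amp0 <- max(m) - off0

  fit <- NULL
  starts <- list(
    c(amplitude = amp0, tau = tau0, offset = off0),
    c(amplitude = max(m), tau = diff(range(times)), offset = 0),
    c(amplitude = diff(range(m)), tau = diff(range(times)) / 3, offset = min(m))
  )
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        m ~ amplitude * exp(-times / tau) + offset,
        start = as.list(st),
        lower = c(amplitude = 0, tau = 1e-9, offset = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("bleach_fit_failed")
  p <- stats::coef(fit)
  model <- list(
    amplitude = unname(p["amplitude"]), tau = unname(p["tau"]),
    offset = unname(p["offset"]),
    fit_residual = sqrt(mean(stats::residuals(fit)^2)),
    frame_means = m, times = times
  )
  if (model$tau <= 0 || model$amplitude < 0) stop("bleach_fit_failed")
  class(model) <- "bleach_model"
  model
}

#' Predicted frame mean of a bleach model
#'
#' @param model a `bleach_model`.
#' @param times times (s) at which to evaluate.
#' @return numeric vector `amplitude * exp(-times / tau) + offset`.
#' @export
predict_bleach <- function(model, times) {
  model$amplitude * exp(-times / model$tau) + model$offset
}

#' Correct photobleaching
#'
#' Multiplies frame `t` by `m(0) / m(t)` where `m` is the fitted bleach
#' model; each frame is scaled by a single scalar, so spatial patterns within
#' a frame are unchanged.
#'
#' @param stack 3-D numeric array `[row, col, frame]`.
#' @param model a `bleach_model` from [fit_bleach()].
#' @param times frame times in seconds; default `model$times`.
#' @return corrected stack.
#' @export
correct_bleach <- function(stack, model, times = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, model$tau > 0)
  nt <- dim(stack)[3]
  if (is.null(times)) times <- model$times
  stopifnot(length(times) == nt)
  m <- predict_bleach(model, times)
  if (any(m <= 0)) stop("correct_bleach: model predicts non-positive mean")
  scale <- m[1] / m
  sweep(stack, 3, scale, "*")
}

#' Ratio-based photobleach fallback correction
#'
#' Divides each frame by its mean over the fit region, normalized to frame 1.
#' A model-free fallback used when the exponential fit fails; on stacks with
#' recruitment it is biased (the signal itself inflates the frame mean),
#' which is why the exponential fit with an exclusion region is the default.
#'
#' @inheritParams fit_bleach
#' @return corrected stack.
#' @export
correct_bleach_ratio <- function(stack, exclude_region = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nt <- dim(stack)[3]
  keep_for <- frame_keep_fun(exclude_region, dim(stack),
                             "correct_bleach_ratio")
  m <- vapply(seq_len(nt), function(i) {
    mean(stack[, , i][keep_for(i)], na.rm = TRUE)
  }, numeric(1))
  if (any(m <= 0)) stop("correct_bleach_ratio: non-positive frame mean")
  sweep(stack, 3, m[1] / m, "*")
}

# Per-frame keep-pixel selector from a static (matrix) or per-frame (3-D
# array) exclusion region.
frame_keep_fun <- function(exclude_region, stack_dim, caller) {
  if (is.null(exclude_region)) {
    keep <- rep(TRUE, prod(stack_dim[1:2]))
    return(function(i) keep)
  }
  if (length(dim(exclude_region)) == 3) {
    stopifnot(all(dim(exclude_region) == stack_dim))
    keeps <- lapply(seq_len(stack_dim[3]), function(i) {
      k <- !as.vector(exclude_region[, , i])
      if (!any(k)) stop(caller, ": exclude_region covers the whole frame")
      k
    })
    return(function(i) keeps[[i]])
  }
  stopifnot(all(dim(exclude_region) == stack_dim[1:2]))
  keep <- !as.vector(exclude_region)
  if (!any(keep)) stop(caller, ": exclude_region covers the whole frame")
  function(i) keep
}
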