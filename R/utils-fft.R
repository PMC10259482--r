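# Internal FFT helpers shared by the registration and simulation code.
# All images are numeric matrices indexed [row, col]; stacks are 3-D arrays
# [row, col, frame].

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# DFT sample frequencies in cycles/pixel, matching the usual fftfreq layout:
# 0, 1/n, ..., then the negative frequencies.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / n
}

# Phase ramp for a translation by (dy, dx) pixels (periodic boundary).
# Positive dy moves content toward larger row indices:
#   out[y, x] ~= img[y - dy, x - dx].
# Nyquist bins are forced real (cosine) so that the shifted spectrum of a
# real image stays Hermitian and the translation is a real operation.
shift_phase_ramp <- function(nr, nc, dy, dx) {
  ramp_1d <- function(n, d) {
    r <- exp(-2i * pi * fft_freq(n) * d)
    if (n %% 2 == 0) r[n / 2 + 1] <- Re(r[n / 2 + 1])
    r
  }
  outer(ramp_1d(nr, dy), ramp_1d(nc, dx))
}

# Sub-pixel translation via the Fourier shift theorem. Values are not
# renormalized; the frame mean is preserved exactly (the DC term is untouched).
fourier_shift <- function(img, dy, dx) {
  stopifnot(is.matrix(img), is.finite(dy), is.finite(dx))
  if (dy == 0 && dx == 0) return(img)
  ramp <- shift_phase_ramp(nrow(img), ncol(img), dy, dx)
  Re(ifft2(fft2(img) * ramp))
}

# Same translation applied from a precomputed spectrum (used by the simulator,
# where one base scene is shifted many times).
fourier_shift_from_spectrum <- function(spectrum, nr, nc, dy, dx) {
  if (dy == 0 && dx == 0) return(Re(ifft2(spectrum)))
  Re(ifft2(spectrum * shift_phase_ramp(nr, nc, dy, dx)))
}

# Gaussian blur implemented as multiplication of the spectrum by the
# Gaussian transfer function exp(-2 pi^2 sigma^2 f^2). Periodic boundary;
# preserves the image mean exactly and remains well defined when the kernel
# support exceeds the frame (the regime of pseudo-flat-field estimation).
gaussian_blur_fft <- function(img, sigma_px) {
  stopifnot(is.matrix(img), sigma_px > 0)
  fy <- fft_freq(nrow(img))
  fx <- fft_freq(ncol(img))
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, "+"))
  Re(ifft2(fft2(img) * h))
}

# Upsampled inverse DFT of a small neighbourhood by explicit matrix multiply
# (the matrix-multiply DFT of Guizar-Sicairos-style sub-pixel registration).
# Evaluates the inverse DFT of `spec` (an nr x nc spectrum) on an
# nor x noc grid of points spaced 1/usfac pixels, with the grid origin at
# (roff, coff) in upsampled units.
dft_upsample <- function(spec, nor, noc, usfac, roff, coff) {
  nr <- nrow(spec)
  nc <- ncol(spec)
  fr <- fft_freq(nr) * nr # integer frequency indices, fftfreq order
  fc <- fft_freq(nc) * nc
  kern_r <- exp(2i * pi / (nr * usfac) * outer((0:(nor - 1)) - roff, fr))
  kern_c <- exp(2i * pi / (nc * usfac) * outer(fc, (0:(noc - 1)) - coff))
  kern_r %*% spec %*% kern_c
}
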