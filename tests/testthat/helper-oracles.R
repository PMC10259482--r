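# Shared fixtures and independent oracles used across test files.

# Broadband test image: white noise with some added low-frequency content.
test_scene <- function(nr, nc = nr, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  m + 0.5 * m[c(2:nr, 1), ] + 0.25 * m[, c(2:nc, 1)]
}

# Circular shift with the package's sign convention:
# result[y, x] == m[y - dy, x - dx] (content moves by +dy rows, +dx cols).
circ_shift <- function(m, dy, dx) {
  nr <- nrow(m)
  nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# Brute-force integer-lag circular cross-correlation argmax (no FFT).
# For each row lag the column-lag scores are diagonal sums of
# crossprod(img, row-shifted ref); returns the signed argmax lag.
brute_force_shift <- function(img, ref) {
  nr <- nrow(ref)
  nc <- ncol(ref)
  best <- -Inf
  best_lag <- c(0L, 0L)
  cseq <- seq_len(nc)
  for (dy in 0:(nr - 1)) {
    rows <- ((seq_len(nr) - 1 - dy) %% nr) + 1
    d <- crossprod(img, ref[rows, , drop = FALSE])
    for (dx in 0:(nc - 1)) {
      cols <- ((cseq - 1 - dx) %% nc) + 1
      s <- sum(d[cbind(cseq, cols)])
      if (s > best) {
        best <- s
        best_lag <- c(dy, dx)
      }
    }
  }
  if (best_lag[1] > nr %/% 2) best_lag[1] <- best_lag[1] - nr
  if (best_lag[2] > nc %/% 2) best_lag[2] <- best_lag[2] - nc
  c(dy = best_lag[1], dx = best_lag[2])
}

# Independent sub-pixel Fourier translation oracle, written directly against
# stats::fft (plain complex phase ramp, no Nyquist handling) -- a separate
# code path from the package's translation.
oracle_fourier_shift <- function(img, dy, dx) {
  nr <- nrow(img)
  nc <- ncol(img)
  freq <- function(n) {
    k <- 0:(n - 1)
    k[k > n %/% 2] <- k[k > n %/% 2] - n
    k / n
  }
  ramp <- exp(-2i * pi * outer(freq(nr) * dy, freq(nc) * dx, `+`))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE) / (nr * nc))
}

# Small, fast generator configuration for unit tests: noise-free, static,
# non-bleaching by default; override any field.
quick_config <- function(...) {
  defaults <- list(
    image_size = c(96L, 96L), n_pre_frames = 5L, n_post_frames = 15L,
    crop_size = 41L, drift_per_frame = c(0, 0), gaussian_sd = 0,
    bleach_tau = Inf, seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Minimum distance (px) from points to a segment, by dense sampling of the
# segment -- an oracle independent of the package's analytic distance.
oracle_segment_distance <- function(x, y, p1, p2, n_samples = 2000) {
  tt <- seq(0, 1, length.out = n_samples)
  sx <- p1[1] + tt * (p2[1] - p1[1])
  sy <- p1[2] + tt * (p2[2] - p1[2])
  vapply(seq_along(x), function(i) {
    sqrt(min((x[i] - sx)^2 + (y[i] - sy)^2))
  }, numeric(1))
}
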