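# Shared fixtures and independent oracles used across the suite.

# DFT sample frequencies (cycles per unit), duplicated here so oracles do
# not lean on package internals.
fftFreqs <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Band-limited random complex field (fraction of Nyquist kept).
bandLimitedField <- function(n, pitch = 1.67, keep = 0.6, seed = 1) {
  set.seed(seed)
  m <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  Fm <- fft(m)
  fr <- sqrt(outer(fftFreqs(n, pitch)^2, fftFreqs(n, pitch)^2, `+`))
  Fm[fr > keep / (2 * pitch)] <- 0
  fft(Fm, inverse = TRUE) / (n * n)
}

# Subpixel translation by Fourier phase ramp (content moves +dx, +dy).
fourierShift <- function(m, dy, dx) {
  fy <- fftFreqs(nrow(m)); fx <- fftFreqs(ncol(m))
  Re(fft(fft(m) * exp(-2i * pi * outer(fy * dy, fx * dx, `+`)),
         inverse = TRUE)) / length(m)
}

# Direct Rayleigh-Sommerfeld summation of a sampled source distribution:
# spatial-domain kernel sum, independent of any FFT method. Source pixels
# are subdivided subSamp x subSamp for the quadrature.
rsDirect <- function(src, pitch, lam, z, probeX, probeY, subSamp = 3) {
  k <- 2 * pi / lam
  n <- nrow(src)
  cx <- (n %/% 2) + 1
  xy <- (seq_len(n) - cx) * pitch
  sub <- (seq_len(subSamp) - (subSamp + 1) / 2) / subSamp * pitch
  tot <- 0 + 0i
  for (sy in sub) for (sx in sub) {
    r <- sqrt(outer((probeY - (xy + sy))^2, (probeX - (xy + sx))^2, `+`) + z^2)
    h <- (1 / (2 * pi)) * (z / r^2) * (1i * k - 1 / r) * exp(1i * k * r)
    tot <- tot + sum(src * h)
  }
  tot * pitch^2 / subSamp^2
}

# Small hologram video with pure translational drift of a band-limited
# random background (used by the drift tests).
driftVideo <- function(n = 64, nf = 12, vx = 0.3, vy = 0, seed = 5) {
  base <- Re(bandLimitedField(n, keep = 0.5, seed = seed))
  frames <- array(0, c(n, n, nf))
  for (i in seq_len(nf))
    frames[, , i] <- fourierShift(base, vy * (i - 1), vx * (i - 1)) + 2
  hologramVideo(frames, frameRate = 26.7, modulationPeriod = 0.0749)
}

# tiny deterministic labelled 4D tensors for classifier unit tests
toyVideoSet <- function(n = 10, shape = c(2, 24, 16, 16), seed = 3) {
  set.seed(seed)
  x <- array(rnorm(prod(shape) * n), c(shape, n))
  y <- rep(c(0L, 1L), length.out = n)
  # make the classes linearly separable through the mean level
  for (i in seq_len(n)) x[, , , , i] <- x[, , , , i] + y[i] * 0.8
  list(x = x, y = y)
}
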