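# Angular-spectrum propagation and spatial filtering.

pitch <- 1.67
lam <- 0.65

test_that("a uniform plane wave is an eigenmode of propagation", {
  f <- complexField(matrix(1 + 0i, 32, 32), pitch, lam)
  g <- angularSpectrumPropagate(f, 1234, padFactor = 1)
  expect_lt(max(abs(Mod(g@values) - 1)), 1e-12)
  # and zero distance is the identity regardless of padding
  expect_identical(angularSpectrumPropagate(f, 0)@values, f@values)
})

test_that("propagation is invertible and energy-conserving on band-limited fields", {
  m <- bandLimitedField(64, pitch, keep = 0.6, seed = 1)
  f <- complexField(m, pitch, lam)
  fwd <- angularSpectrumPropagate(f, 1200, padFactor = 1)
  back <- angularSpectrumPropagate(fwd, -1200, padFactor = 1)
  expect_lt(max(Mod(back@values - m)) / max(Mod(m)), 1e-9)
  expect_lt(abs(sum(Mod(fwd@values)^2) / sum(Mod(m)^2) - 1), 1e-9)
})

test_that("propagation matches a direct Rayleigh-Sommerfeld oracle at probe pixels", {
  # a near-point source: a narrow Gaussian spot is band-limited on the
  # grid, so the spatial-domain kernel sum and the spectral method must
  # agree (a hard single-pixel source is not representable to 1%)
  n <- 64
  xy <- seq_len(n) - 33
  src <- exp(-outer(xy^2, xy^2, `+`) / (2 * 2^2))
  out <- angularSpectrumPropagate(complexField(src + 0i, pitch, lam), 1000,
                                  padFactor = 8)
  probes <- rbind(c(0, 0), c(3, 0), c(0, 3), c(-3, 0), c(0, -3),
                  c(5, 5), c(-5, 5), c(8, 0), c(0, 8))
  for (p in seq_len(nrow(probes))) {
    dx <- probes[p, 1]; dy <- probes[p, 2]
    got <- Mod(out@values[33 + dy, 33 + dx])^2
    # oracle: RS kernel sum against the continuous Gaussian source
    want <- Mod(rsDirect(src, pitch, lam, 1000, dx * pitch, dy * pitch))^2
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("undersampled wavelengths warn and invalid fields are rejected", {
  f <- complexField(matrix(1 + 0i, 8, 8), pixelPitch = 0.3, wavelength = 0.65)
  expect_warning(angularSpectrumPropagate(f, 100), "undersamples")
  expect_error(complexField(matrix(c(NaN, rep(1, 15)), 4, 4), pitch, lam),
               "finite")
  expect_error(angularSpectrumPropagate(
    complexField(matrix(1 + 0i, 8, 8), pitch, lam), Inf), "finite")
})

test_that("the Gaussian high-pass removes DC and preserves the pass band", {
  f <- complexField(matrix(5 + 0i, 32, 32), pitch, lam)
  out <- highPassFilter(f, filterSpec(cutoff = 0.05))
  expect_lt(max(Mod(out@values)), 1e-12 * 5)
  # pure sinusoid at 0.9 x Nyquist passes essentially unchanged
  n <- 32
  fx <- round(0.9 * n / 2) / (n * pitch)
  carrier <- cos(2 * pi * fx * (seq_len(n) - 1) * pitch)
  s <- complexField(matrix(carrier, n, n, byrow = TRUE) + 0i, pitch, lam)
  outs <- highPassFilter(s, filterSpec(cutoff = 0.01))
  expect_lt(max(Mod(outs@values - s@values)) / max(Mod(s@values)), 0.01)
})

test_that("filter attenuation matches the closed-form transfer function", {
  n <- 32
  kcar <- 6
  fcar <- kcar / (n * pitch)
  cutoff <- 0.05
  carrier <- cos(2 * pi * kcar * (seq_len(n) - 1) / n)
  mix <- 2 + matrix(carrier, n, n, byrow = TRUE)   # DC + carrier
  out <- highPassFilter(complexField(mix + 0i, pitch, lam),
                        filterSpec(cutoff = cutoff))
  # carrier amplitude after filtering, via projection onto the carrier
  amp <- 2 * abs(mean(out@values[1, ] * exp(-2i * pi * kcar * (seq_len(n) - 1) / n)))
  want <- 1 - exp(-fcar^2 / (2 * cutoff^2))       # direct transfer evaluation
  expect_equal(amp, want, tolerance = 1e-9)
  # DC response is exactly zero
  expect_lt(abs(mean(out@values)), 1e-12)
})

test_that("filtered back-propagation composes the two operations over the grid", {
  grid <- depthGrid()
  expect_length(zValues(grid), 43L)
  m <- Re(bandLimitedField(16, pitch, keep = 0.8, seed = 2))
  st <- filteredBackpropagate(m, depthGrid(1000, 1300, 100),
                              pixelPitch = pitch, wavelength = lam)
  expect_identical(dim(st), c(16L, 16L, 4L))
  f <- complexField(m, pitch, lam)
  for (j in 1:4) {
    want <- highPassFilter(angularSpectrumPropagate(f, -(900 + j * 100)),
                           filterSpec())@values
    expect_identical(st[, , j], want)
  }
  expect_error(new("DepthGrid", z = numeric(0), step = 1), "non-empty")
})

test_that("a simulated particle reconstructs at its depth plane", {
  objs <- list(simObject("static_particle", x = 64, y = 64, z = 500,
                         radius = 2.5, amplitude = 0.8, phase = 1))
  sc <- sceneSpec(fov = c(128L, 128L), objects = objs,
                  driftVelocity = c(0, 0),
                  background = list(speckleAmplitude = 0, grain = 3),
                  sensor = list(bitDepth = 10L, gain = 260, readNoise = 0,
                                shotNoise = FALSE),
                  nFrames = 4L, frameRate = 26.7, modulationPeriod = 0.0749,
                  seed = 9)
  fr <- renderHologramVideo(sc)$video@frames[, , 1]
  st <- filteredBackpropagate(fr / mean(fr) - 1, depthGrid(200, 800, 100),
                              pixelPitch = pitch, wavelength = lam,
                              padFactor = 1)
  peak <- vapply(1:7, function(j) max(Mod(st[33:96, 33:96, j])), numeric(1))
  zbest <- seq(200, 800, 100)[which.max(peak)]
  expect_lte(abs(zbest - 500), 100)  # within one grid step
  # and the in-plane argmax sits at the particle centroid
  plane <- Mod(st[, , which.max(peak)])
  at <- which(plane == max(plane), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(at - c(64, 64))), 2)
})

test_that("the focus window spans 66.8 um at the sensor pitch", {
  expect_equal(focusWindowExtent(1.67), 66.8)
})
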