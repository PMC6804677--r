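# Periodic-motion contrast, projection, and candidate detection.

makeStacks <- function(fun, nf = 8, d = c(4, 4, 2)) {
  B <- array(0 + 0i, c(d, nf))
  for (i in seq_len(nf)) B[, , , i] <- fun(i)
  B
}

test_that("time-constant stacks give exactly zero contrast", {
  B <- makeStacks(function(i) matrix(2 + 3i, 4, 4))
  vol <- cmaContrast(B, N = 4)
  expect_true(all(contrastValues(vol) == 0))
})

test_that("half-period alternation gives |P - Q| and a ramp gives -(N/2)|G|", {
  P <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  Q <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  N <- 4
  B <- makeStacks(function(i) if (((i - 1) %/% (N / 2)) %% 2 == 0) P else Q,
                  nf = 12)
  vol <- cmaContrast(B, N = N, differences = "complex")
  expect_equal(contrastValues(vol)[, , 1], Mod(P - Q), tolerance = 1e-12)
  # with amplitude-image differences the same identity holds on |P|, |Q|
  volM <- cmaContrast(B, N = N, differences = "magnitude")
  expect_equal(contrastValues(volM)[, , 1], abs(Mod(P) - Mod(Q)),
               tolerance = 1e-12)

  G <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  B <- makeStacks(function(i) i * G, nf = 12)
  for (conv in c("complex", "magnitude")) {
    vol <- cmaContrast(B, N = N, differences = conv)
    expect_equal(contrastValues(vol)[, , 1], -(N / 2) * Mod(G),
                 tolerance = 1e-12)
  }
})

test_that("monotonic trajectories give non-positive contrast", {
  set.seed(8)
  base <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  step <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  # per-pixel monotonic-in-time motion along a line in the complex plane
  B <- makeStacks(function(i) base + sqrt(i) * step, nf = 10)
  vol <- cmaContrast(B, N = 4, differences = "complex")
  expect_true(all(contrastValues(vol) <= 1e-12))
})

test_that("adding a static field to every frame leaves the contrast unchanged", {
  # exact for complex differences, where the offset cancels algebraically
  set.seed(9)
  B <- makeStacks(function(i) matrix(complex(real = rnorm(16),
                                             imaginary = rnorm(16)), 4, 4),
                  nf = 8, d = c(4, 4, 1))
  B2 <- B + (5 - 2i)
  v1 <- contrastValues(cmaContrast(B, N = 4, differences = "complex"))
  v2 <- contrastValues(cmaContrast(B2, N = 4, differences = "complex"))
  expect_lt(max(abs(v1 - v2)), 1e-9 * max(abs(v1)))
})

test_that("invalid N is rejected", {
  B <- makeStacks(function(i) matrix(0i, 4, 4), nf = 6)
  expect_error(cmaContrast(B, N = 3), "even")
  expect_error(cmaContrast(B, N = 6), "smaller")
})

test_that("cmaContrast accepts per-frame stack lists and matches the array path", {
  set.seed(10)
  B <- makeStacks(function(i) matrix(complex(real = rnorm(16),
                                             imaginary = rnorm(16)), 4, 4),
                  nf = 8)
  asList <- lapply(1:8, function(i) B[, , , i, drop = FALSE][, , , 1])
  expect_equal(contrastValues(cmaContrast(asList, N = 4)),
               contrastValues(cmaContrast(B, N = 4)))
})

test_that("streamed motion contrast equals stacking filteredBackpropagate", {
  set.seed(11)
  frames <- array(runif(24 * 24 * 8, 100, 200), c(24, 24, 8))
  v <- hologramVideo(frames, frameRate = 26.7, modulationPeriod = 0.15)
  grid <- depthGrid(900, 1100, 100)
  stacks <- lapply(1:8, function(i)
    filteredBackpropagate(frames[, , i], grid, filterSpec(), padFactor = 1,
                          pixelPitch = 1.67, wavelength = 0.65))
  direct <- cmaContrast(stacks, N = 4, grid = grid)
  streamed <- motionContrastVolume(v, grid, N = 4, padFactor = 1)
  expect_equal(contrastValues(streamed), contrastValues(direct),
               tolerance = 1e-12)
})

test_that("maximum intensity projection equals the brute-force per-pixel scan", {
  set.seed(12)
  vals <- array(rnorm(10 * 12 * 5), c(10, 12, 5))
  vol <- new("MotionContrastVolume", values = vals,
             grid = depthGrid(1000, 1400, 100))
  D <- projectMaxIntensity(vol)
  brute <- apply(vals, c(1, 2), max)
  expect_identical(D, brute)
  one <- new("MotionContrastVolume", values = vals[, , 1, drop = FALSE],
             grid = depthGrid(1000, 1000, 100))
  expect_identical(projectMaxIntensity(one), vals[, , 1])
})

test_that("detection finds blobs, flags borders and ignores empty maps", {
  expect_identical(nrow(detectCandidates(matrix(0, 64, 64))), 0L)

  xy <- seq_len(96)
  blob <- function(cx, cy, a) a * exp(-outer((xy - cy)^2, (xy - cx)^2, `+`) / 18)
  set.seed(13)
  noise <- matrix(rnorm(96^2, 0, 0.1), 96)
  map <- blob(30.3, 40.7, 10) + blob(70.2, 60.4, 8) + noise
  cands <- detectCandidates(map, threshold = list(policy = "adaptive", kappa = 6),
                            minArea = 4L, borderMargin = 8L)
  expect_identical(nrow(cands), 2L)
  cands <- cands[order(cands$x), ]
  expect_lt(abs(cands$x[1] - 30.3), 1)
  expect_lt(abs(cands$y[1] - 40.7), 1)
  expect_lt(abs(cands$x[2] - 70.2), 1)
  expect_false(any(cands$border))

  # blob near the border is flagged; absolute thresholds work
  mapB <- blob(5, 48, 10)
  cb <- detectCandidates(mapB, threshold = 3, minArea = 4L, borderMargin = 8L)
  expect_true(all(cb$border))
})

test_that("components are labelled with 8-connectivity and small ones dropped", {
  map <- matrix(0, 16, 16)
  map[cbind(c(4, 5, 6, 7), c(4, 5, 6, 7))] <- 10   # diagonal chain, area 4
  cands <- detectCandidates(map, threshold = 1, minArea = 4L, borderMargin = 0L)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$area, 4L)
  cands <- detectCandidates(map, threshold = 1, minArea = 5L, borderMargin = 0L)
  expect_identical(nrow(cands), 0L)
})
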