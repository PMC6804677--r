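# Coarse/fine autofocusing and candidate-video extraction.

test_that("coarse autofocus equals an exhaustive windowed-sum oracle", {
  set.seed(31)
  for (trial in 1:3) {
    vals <- array(rnorm(40 * 40 * 7), c(40, 40, 7))
    vol <- new("MotionContrastVolume", values = vals,
               grid = depthGrid(1000, 1600, 100))
    cand <- list(x = runif(1, 5, 36), y = runif(1, 5, 36))
    got <- autofocusCoarse(vol, cand)
    # oracle: brute-force sum over the clipped window at every plane
    ys <- intersect(round(cand$y) + (-19:20), 1:40)
    xs <- intersect(round(cand$x) + (-19:20), 1:40)
    want <- which.max(vapply(1:7, function(j) sum(vals[ys, xs, j]), numeric(1)))
    expect_identical(got$index, want)
    expect_identical(got$z, zValues(vol@grid)[want])
  }
})

test_that("localised contrast bumps are found at their planes, windows clip", {
  vals <- array(0, c(64, 64, 40))
  bump <- function(cx, cy) outer(exp(-((1:64) - cy)^2 / 8),
                                 exp(-((1:64) - cx)^2 / 8))
  vals[, , 17] <- bump(20, 20)
  vals[, , 30] <- bump(50, 50)
  vol <- new("MotionContrastVolume", values = vals,
             grid = depthGrid(800, 4700, 100))
  expect_identical(autofocusCoarse(vol, list(x = 20, y = 20))$index, 17L)
  expect_identical(autofocusCoarse(vol, list(x = 50, y = 50))$index, 30L)
  # corner candidate: clipped window still matches the oracle
  vals2 <- array(rnorm(64 * 64 * 5), c(64, 64, 5))
  vol2 <- new("MotionContrastVolume", values = vals2,
              grid = depthGrid(800, 1200, 100))
  got <- autofocusCoarse(vol2, list(x = 2, y = 3))
  ys <- intersect(3 + (-19:20), 1:64); xs <- intersect(2 + (-19:20), 1:64)
  want <- which.max(vapply(1:5, function(j) sum(vals2[ys, xs, j]), numeric(1)))
  expect_identical(got$index, want)
})

test_that("flat volumes trigger the deterministic tie-break with a warning", {
  vol <- new("MotionContrastVolume", values = array(1, c(48, 48, 5)),
             grid = depthGrid(800, 1200, 100))
  expect_warning(got <- autofocusCoarse(vol, list(x = 24, y = 24)),
                 "degenerate")
  expect_identical(got$index, 1L)
  v <- hologramVideo(array(7, c(48, 48, 24)), frameRate = 12)
  expect_warning(rf <- autofocusRefine(v, list(x = 24, y = 24), 1000,
                                       region = 48L, zRange = c(800, 5000)),
                 "flat")
  expect_identical(rf$z, 1000)
})

test_that("the fine grid is clamped to the allowed depth range", {
  v <- hologramVideo(array(7, c(48, 48, 24)), frameRate = 12)
  expect_warning(rf <- suppressWarnings(
    autofocusRefine(v, list(x = 24, y = 24), 850, region = 48L,
                    zRange = c(800, 5000))), regexp = NA)
  rf2 <- withCallingHandlers(
    autofocusRefine(v, list(x = 24, y = 24), 850, region = 48L,
                    zRange = c(900, 5000)),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(all(rf2$zGrid >= 900))
})

test_that("refinement recovers a depth between coarse planes", {
  obj <- simObject("oscillating_cell", x = 48, y = 48, z = 860)
  sc <- deskScene(seed = 33, objects = list(obj))
  sim <- renderHologramVideo(sc)
  vid <- correctDrift(sim$video, estimateDrift(sim$video))
  vol <- motionContrastVolume(vid, deskDepthGrid())
  cf <- autofocusCoarse(vol, list(x = 48, y = 48))
  rf <- suppressWarnings(
    autofocusRefine(vid, list(x = 48, y = 48), cf$z, region = 96L,
                    zRange = range(zValues(deskDepthGrid()))))
  # the desk field of view subtends NA ~ 0.09 at this depth, a depth of
  # focus near 75 um: require agreement at that scale
  expect_lte(abs(rf$z - 860), 150)
})

test_that("candidate videos have the contract shape, ranges and border padding", {
  obj <- simObject("oscillating_cell", x = 40, y = 40, z = 900)
  sc <- deskScene(seed = 34, objects = list(obj))
  sim <- renderHologramVideo(sc)
  vid <- correctDrift(sim$video, estimateDrift(sim$video))
  cv <- extractCandidateVideo(vid, list(x = 40, y = 40), 900, crop = 16L,
                              id = 3L)
  v <- videoValues(cv)
  expect_identical(dim(v), c(2L, 24L, 16L, 16L))
  expect_true(all(v[1, , , ] >= 0))
  expect_true(all(v[2, , , ] > -pi - 1e-12 & v[2, , , ] <= pi + 1e-12))
  expect_identical(cv@candidateId, 3L)
  # amplitude normalised to unit 99th percentile
  expect_equal(unname(quantile(v[1, , , ], 0.99)), 1, tolerance = 1e-9)

  # candidate near the border: out-of-bounds area is zero-padded and the
  # in-bounds pixels agree with the unclipped full-field computation
  cvB <- extractCandidateVideo(vid, list(x = 5, y = 40), 900, crop = 16L,
                               normalize = FALSE)
  vb <- videoValues(cvB)
  expect_true(all(vb[1, , , 1:3] == 0))   # columns beyond the left edge
  B1 <- holocyte:::.hpApply(
    holocyte:::.asPropagate(vid@frames[, , 1] + 0i, -900, vid@pixelPitch,
                            vid@wavelength, 1),
    vid@pixelPitch, filterSpec()@cutoff)
  expect_equal(vb[1, 1, , 4:16], Mod(B1)[33:48, 1:13], tolerance = 1e-9)
  expect_error(extractCandidateVideo(vid, list(x = 200, y = 40), 900),
               "outside")
})

test_that("the amplitude channel is sharpest at the refined focus plane", {
  obj <- simObject("oscillating_cell", x = 48, y = 48, z = 900)
  sc <- deskScene(seed = 35, objects = list(obj))
  sim <- renderHologramVideo(sc)
  vid <- correctDrift(sim$video, estimateDrift(sim$video))
  varAt <- function(z) {
    v <- videoValues(extractCandidateVideo(vid, list(x = 48, y = 48), z,
                                           crop = 16L, normalize = FALSE))
    stats::var(as.vector(v[1, 1, , ]))
  }
  expect_gt(varAt(900), varAt(400))
  expect_gt(varAt(900), varAt(1400))
})
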