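# Synthetic hologram scenes: trajectories, rendering, determinism, and
# class separation of the motion contrast.

test_that("oscillating cells sit at the extremes at multiples of the half period", {
  obj <- simObject("oscillating_cell", x = 32, y = 32, z = 1000,
                   motion = list(relaxTime = 0.02))
  sc <- sceneSpec(fov = c(64L, 64L), objects = list(obj),
                  driftVelocity = c(0, 0), frameRate = 20, nFrames = 41L,
                  seed = 1)
  tr <- objectTrajectory(obj, seq_len(41), sc)
  rot <- obj$motion$rotAmplitude
  # t = 0, 1 s, 2 s: extreme A (theta = +rot); t = 0.5, 1.5 s: extreme B
  expect_equal(tr$theta[1], rot, tolerance = 1e-6)
  expect_equal(tr$theta[21], rot, tolerance = 1e-6)   # t = 1 s
  expect_equal(tr$theta[41], rot, tolerance = 1e-6)   # t = 2 s
  expect_equal(tr$theta[11], -rot, tolerance = 1e-6)  # t = 0.5 s
  expect_equal(tr$theta[31], -rot, tolerance = 1e-6)
})

test_that("static particles advance exactly with the scene drift", {
  obj <- simObject("static_particle", x = 20, y = 30, z = 1000)
  sc <- sceneSpec(fov = c(64L, 64L), objects = list(obj),
                  driftVelocity = c(0.1, 0), frameRate = 12, nFrames = 24L,
                  seed = 1)
  tr <- objectTrajectory(obj, seq_len(24), sc)
  expect_equal(tr$x, 20 + 0.1 * (0:23))
  expect_equal(tr$y, rep(30, 24))
  expect_equal(tr$theta, rep(0, 24))
})

test_that("random walkers follow 2 D t mean-squared displacement", {
  Dcoef <- 0.25
  nW <- 300L
  lag <- 200L
  starts <- c(1L, 201L, 401L, 601L, 801L)
  sc <- sceneSpec(fov = c(64L, 64L), driftVelocity = c(0, 0), frameRate = 12,
                  nFrames = 1001L, modulationPeriod = 1, seed = 42,
                  objects = lapply(seq_len(nW), function(i)
                    simObject("random_walker", x = 32, y = 32, z = 1000,
                              motion = list(diffusion = Dcoef))))
  # non-overlapping lag windows on both axes across all walkers
  sq <- unlist(lapply(sc@objects, function(o) {
    tr <- objectTrajectory(o, c(starts, starts + lag), sc)
    k <- length(starts)
    c((tr$x[(k + 1):(2 * k)] - tr$x[1:k])^2,
      (tr$y[(k + 1):(2 * k)] - tr$y[1:k])^2)
  }))
  expect_lt(abs(mean(sq) / (2 * Dcoef * lag) - 1), 0.1)
})

test_that("rendering is deterministic and respects the sensor range", {
  sc <- deskScene(seed = 5, objects = list(
    simObject("oscillating_cell", x = 48, y = 48, z = 900)))
  a <- renderHologramVideo(sc)
  b <- renderHologramVideo(sc)
  expect_identical(a$video@frames, b$video@frames)
  expect_identical(a$truth, b$truth)
  bits <- sc@sensor$bitDepth
  expect_true(all(a$video@frames >= 0 & a$video@frames <= 2^bits - 1))
  expect_true(all(a$video@frames == round(a$video@frames)))
})

test_that("an empty noiseless scene renders uniform frames", {
  sc <- sceneSpec(fov = c(32L, 32L), objects = list(),
                  driftVelocity = c(0, 0), frameRate = 12, nFrames = 4L,
                  modulationPeriod = 0.1667,
                  background = list(speckleAmplitude = 0, grain = 3),
                  sensor = list(bitDepth = 10L, gain = 260, readNoise = 0,
                                shotNoise = FALSE), seed = 2)
  out <- renderHologramVideo(sc)
  expect_identical(length(unique(as.vector(out$video@frames))), 1L)
})

test_that("motion contrast separates cells from walkers from static debris", {
  objs <- list(
    simObject("oscillating_cell", x = 28, y = 28, z = 700),
    simObject("oscillating_cell", x = 68, y = 68, z = 850),
    simObject("random_walker", x = 28, y = 68, z = 600,
              motion = list(diffusion = 0.3)),
    simObject("random_walker", x = 48, y = 20, z = 900,
              motion = list(diffusion = 0.3)),
    simObject("static_particle", x = 68, y = 28, z = 750),
    simObject("static_particle", x = 20, y = 48, z = 800))
  sc <- deskScene(seed = 21, objects = objs)
  sim <- renderHologramVideo(sc)
  vid <- correctDrift(sim$video, estimateDrift(sim$video))
  vol <- motionContrastVolume(vid, deskDepthGrid())
  D <- projectMaxIntensity(vol)
  peakAt <- function(x, y) {
    xs <- pmax(1, round(x) - 4):pmin(ncol(D), round(x) + 4)
    ys <- pmax(1, round(y) - 4):pmin(nrow(D), round(y) + 4)
    max(D[ys, xs])
  }
  tru <- sim$truth
  pk <- vapply(seq_len(nrow(tru)),
               function(i) peakAt(tru$xRef[i], tru$yRef[i]), numeric(1))
  med <- tapply(pk, tru$kind, stats::median)
  expect_gt(med[["oscillating_cell"]], med[["random_walker"]])
  expect_gt(med[["random_walker"]], med[["static_particle"]])
})

test_that("labelled datasets are balanced, matched to truth and seed-disjoint", {
  ds <- generateLabelledDataset(3, kinds = c("bead_chain", "oscillating_cell"),
                                seed = 101, objectsPerScene = 3L)
  expect_identical(unname(unlist(ds$manifest$counts)), c(3L, 3L))
  expect_identical(as.vector(table(ds$labels)), c(3L, 3L))
  expect_identical(length(ds$videos), 6L)
  expect_true(all(vapply(ds$videos, function(v)
    identical(dim(videoValues(v)), c(2L, 24L, 16L, 16L)), logical(1))))
  # lateral match of detection and truth is within the match tolerance
  expect_true(all(sqrt((ds$truth$x - ds$truth$xDetected)^2 +
                       (ds$truth$y - ds$truth$yDetected)^2) <= 8))
  ds2 <- generateLabelledDataset(2, kinds = c("oscillating_cell"),
                                 seed = 202, objectsPerScene = 3L)
  # disjoint seeds give disjoint data
  a <- videoValues(ds$videos[[which(ds$labels == "oscillating_cell")[1]]])
  for (v in ds2$videos) expect_false(identical(videoValues(v), a))
})
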