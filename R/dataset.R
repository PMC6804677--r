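# Labelled candidate-video datasets from the simulator: scenes are
# rendered, screened with the real detection + focusing pipeline, and the
# resulting crops are labelled by matching detections to the simulator's
# ground truth. Crops that cannot be matched unambiguously are discarded.

#' Generate a labelled candidate-video dataset
#'
#' Renders scenes from the template (each scene holds \code{objectsPerScene}
#' objects of a single motion class at random positions and depths), runs
#' drift correction, motion-contrast screening, detection, fine autofocusing
#' and video extraction, labels each extracted crop by its nearest
#' ground-truth object (within \code{matchTol} px; unmatched or ambiguous
#' detections are dropped) and returns balanced per-class sets with a
#' manifest. The detection threshold used here is looser than the screening
#' default (\code{kappa = 4}) because ground-truth matching removes any
#' false detections it admits.
#'
#' @param nPerClass videos to produce per class.
#' @param kinds character vector of object kinds (the label factor keeps
#'   this order; by convention put the negative class first).
#' @param template a \linkS4class{SceneSpec} providing geometry, noise and
#'   acquisition settings (its own object list is ignored).
#' @param seed master seed; scene seeds derive from it.
#' @param grid \linkS4class{DepthGrid} used for screening.
#' @param objectsPerScene objects rendered per scene.
#' @param crop candidate-video crop side (px).
#' @param refineRegion local neighbourhood for fine autofocusing (px).
#' @param fineStep,fineHalfspan fine autofocus grid (um).
#' @param kappa detection threshold in background standard deviations.
#' @param matchTol ground-truth matching tolerance (px); the default 8
#'   accommodates bead chains, whose motion-contrast lobes sit at the
#'   swinging chain ends rather than the chain centre.
#' @param maxScenesPerClass scene budget per class before giving up.
#' @return list with \code{videos} (list of \linkS4class{CandidateVideo}),
#'   \code{labels} (factor with levels \code{kinds}), \code{truth}
#'   (data.frame of matched ground truth incl. true and refined depth) and
#'   \code{manifest}.
#' @export
generateLabelledDataset <- function(nPerClass, kinds = c("bead_chain", "oscillating_cell"),
                                    template = deskScene(), seed = 1L,
                                    grid = deskDepthGrid(), objectsPerScene = 4L,
                                    crop = 16L, refineRegion = 96L,
                                    fineStep = 10, fineHalfspan = 100,
                                    kappa = 4, matchTol = 8,
                                    maxScenesPerClass = NULL) {
  stopifnot(nPerClass >= 1, length(kinds) >= 1)
  if (is.null(maxScenesPerClass))
    maxScenesPerClass <- ceiling(4 * nPerClass / objectsPerScene) + 5L
  videos <- list(); labels <- character(0); truthRows <- list()
  counts <- stats::setNames(integer(length(kinds)), kinds)
  zr <- range(zValues(grid))
  margin <- crop / 2 + 2
  nScenes <- 0L
  for (kind in kinds) {
    sceneIdx <- 0L
    while (counts[kind] < nPerClass && sceneIdx < maxScenesPerClass) {
      sceneIdx <- sceneIdx + 1L
      sseed <- as.integer((seed + match(kind, kinds) * 131071 +
                           sceneIdx * 9973) %% 2147483647)
      set.seed(sseed)
      fov <- template@fov
      pos <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(pos) < objectsPerScene && tries < 2000L) {
        tries <- tries + 1L
        p <- c(stats::runif(1, margin, fov[2] - margin),
               stats::runif(1, margin, fov[1] - margin))
        if (nrow(pos) == 0 || min(sqrt(rowSums(sweep(pos, 2, p)^2))) >= max(crop, 24L))
          pos <- rbind(pos, p)
      }
      objs <- lapply(seq_len(nrow(pos)), function(k)
        simObject(kind, x = pos[k, 1], y = pos[k, 2],
                  z = stats::runif(1, zr[1] + 100, zr[2] - 100),
                  radius = 7.5,
                  motion = list(phaseOffset = stats::runif(1, 0, 0.05))))
      scene <- sceneSpec(fov = fov, objects = objs,
                         pixelPitch = template@pixelPitch,
                         wavelength = template@wavelength,
                         frameRate = template@frameRate,
                         nFrames = template@nFrames,
                         modulationPeriod = template@modulationPeriod,
                         driftVelocity = template@driftVelocity,
                         background = template@background,
                         sensor = template@sensor,
                         renderWindow = template@renderWindow,
                         seed = sseed)
      sim <- renderHologramVideo(scene)
      nScenes <- nScenes + 1L
      vid <- correctDrift(sim$video, estimateDrift(sim$video), axes = "x")
      N <- framesPerPeriod(vid)
      vol <- motionContrastVolume(vid, grid, N = N)
      D <- projectMaxIntensity(vol)
      cands <- detectCandidates(D, threshold = list(policy = "adaptive",
                                                    kappa = kappa),
                                minArea = 4L, borderMargin = as.integer(crop / 2),
                                minSeparation = 12)
      if (nrow(cands) == 0) next
      for (ci in seq_len(nrow(cands))) {
        dd <- sqrt((sim$truth$xRef - cands$x[ci])^2 + (sim$truth$yRef - cands$y[ci])^2)
        hit <- which(dd <= matchTol)
        if (length(hit) != 1) next      # unmatched or ambiguous: discard
        if (counts[kind] >= nPerClass) break
        cf <- autofocusCoarse(vol, cands[ci, ])
        rf <- suppressWarnings(
          autofocusRefine(vid, cands[ci, ], cf$z, fineStep = fineStep,
                          fineHalfspan = fineHalfspan, N = N,
                          region = refineRegion, zRange = zr))
        cv <- extractCandidateVideo(vid, cands[ci, ], rf$z, crop = crop,
                                    id = length(videos) + 1L)
        videos[[length(videos) + 1L]] <- cv
        labels <- c(labels, kind)
        counts[kind] <- counts[kind] + 1L
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          videoId = length(videos), scene = sseed, kind = kind,
          x = sim$truth$x[hit], y = sim$truth$y[hit],
          xDetected = cands$x[ci], yDetected = cands$y[ci],
          zTrue = sim$truth$z[hit], zCoarse = cf$z, zRefined = rf$z,
          peakScore = cands$peakScore[ci], snr = sim$truth$snr[hit])
      }
    }
    if (counts[kind] == 0)
      stop(sprintf("pipeline recovered zero objects of class '%s'", kind))
  }
  short <- names(counts)[counts < nPerClass]
  if (length(short))
    warning(sprintf("scene budget reached before filling class(es): %s",
                    paste(short, collapse = ", ")))
  list(videos = videos,
       labels = factor(labels, levels = kinds),
       truth = do.call(rbind, truthRows),
       manifest = list(seed = seed, nPerClass = nPerClass, kinds = kinds,
                       counts = as.list(counts), nScenes = nScenes,
                       objectsPerScene = objectsPerScene, crop = crop,
                       kappa = kappa, matchTol = matchTol,
                       fov = template@fov, nFrames = template@nFrames,
                       frameRate = template@frameRate))
}
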