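# Synthetic-data generator: renders magnetically modulated holographic
# speckle videos with full ground truth, so every stage of the pipeline is
# testable without recorded data.
#
# Physics: each object is a weak complex transmittance patch at its depth;
# its scattered field (transmittance minus one) is forward-propagated to
# the sensor by the angular spectrum method and superposed on a unit
# reference wave (single-scattering approximation, adequate for sparse
# scenes). Motion is phenomenological: bead-conjugated cells roll -- a
# square-wave drive with first-order exponential relaxation rotates an
# asymmetric internal bead pattern (appearance, not just position,
# oscillates) and rocks the cell laterally; unbound bead chains swing
# between two orientations at the same drive period; background debris
# performs Brownian motion or stays static; the whole scene drifts slowly.

#' Scene specification for the hologram simulator
#'
#' Holds geometry, acquisition, object list and noise model for one
#' simulated field of view. Defaults mirror the acquisition conditions:
#' 1.67 um pitch, 650 nm wavelength, 26.7 fps, 120 frames, 1 s modulation
#' period.
#'
#' @slot fov c(rows, cols) in pixels.
#' @slot pixelPitch,wavelength,frameRate,nFrames,modulationPeriod acquisition
#'   metadata (um, um, fps, count, s).
#' @slot objects list of objects from \code{\link{simObject}}.
#' @slot driftVelocity c(x, y) scene drift in px/frame.
#' @slot background list: \code{speckleAmplitude} (static speckle field
#'   amplitude relative to the unit reference), \code{grain} (correlation
#'   length, px).
#' @slot sensor list: \code{bitDepth}, \code{gain} (digital numbers per unit
#'   intensity), \code{readNoise} (DN, Gaussian), \code{shotNoise}
#'   (logical, Poisson).
#' @slot renderWindow side of the local window each object is rendered in.
#' @slot seed integer RNG seed; every stochastic element derives from it.
#' @export
setClass("SceneSpec",
  representation(fov = "integer", pixelPitch = "numeric", wavelength = "numeric",
                 frameRate = "numeric", nFrames = "integer",
                 modulationPeriod = "numeric", objects = "list",
                 driftVelocity = "numeric", background = "list",
                 sensor = "list", renderWindow = "integer", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- NULL
  if (any(object@fov < 8)) msg <- c(msg, "fov must be at least 8 px")
  if (object@pixelPitch <= 0 || object@wavelength <= 0 || object@frameRate <= 0 ||
      object@nFrames <= 1 || object@modulationPeriod <= 0)
    msg <- c(msg, "physical quantities must be positive")
  if (length(object@driftVelocity) != 2) msg <- c(msg, "driftVelocity must be length 2")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %d x %d px, %d frames @ %.4g fps, %d objects, seed %d\n",
              object@fov[1], object@fov[2], object@nFrames, object@frameRate,
              length(object@objects), object@seed))
})

#' Simulated object
#'
#' @param kind one of \code{"oscillating_cell"} (bead-conjugated target
#'   cell: square-wave-driven rolling with relaxation), \code{"bead_chain"}
#'   (unbound bead chain swinging at the drive period),
#'   \code{"random_walker"} (Brownian debris), \code{"static_particle"}.
#' @param x,y lateral position in px (1-based, x = column).
#' @param z depth in um.
#' @param radius object radius in um (cell body for cells).
#' @param amplitude,phase amplitude attenuation (0..1) and phase delay
#'   (rad) of the object body.
#' @param motion kind-specific motion parameters; missing entries take the
#'   defaults: cells \code{rotAmplitude} 0.7 rad, \code{oscOffsetPx} 1,
#'   \code{relaxTime} 0.08 s, \code{phaseOffset} 0 s, \code{nBeads} 5,
#'   \code{beadRadius} 2.25 um (4.5 um capture beads); chains
#'   \code{swingAngle} 0.9 rad, \code{relaxTime} 0.03 s, \code{nBeads} 6,
#'   \code{beadRadius} 2.25 um; walkers \code{diffusion} 0.08 px^2/frame
#'   (per-axis step variance 2 x diffusion). The oscillation period always
#'   equals the magnetic drive period of the scene.
#' @return a \code{SimObject} list.
#' @export
simObject <- function(kind = c("oscillating_cell", "bead_chain",
                               "random_walker", "static_particle"),
                      x, y, z, radius = 8, amplitude = 0.6, phase = 1.0,
                      motion = list()) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    oscillating_cell = list(rotAmplitude = 0.7, oscOffsetPx = 1.0,
                            relaxTime = 0.08, phaseOffset = 0, nBeads = 5L,
                            beadRadius = 2.25),
    bead_chain = list(swingAngle = 0.9, relaxTime = 0.03, phaseOffset = 0,
                      nBeads = 6L, beadRadius = 2.25),
    random_walker = list(diffusion = 0.08, seed = NA_integer_),
    static_particle = list())
  motion <- utils::modifyList(defaults, motion)
  structure(list(kind = kind, x = x, y = y, z = z, radius = radius,
                 amplitude = amplitude, phase = phase, motion = motion),
            class = "SimObject")
}

#' Construct a scene specification
#'
#' @param fov c(rows, cols) px.
#' @param objects list of \code{\link{simObject}}s; random walkers without
#'   a seed get one derived deterministically from the scene seed.
#' @param pixelPitch,wavelength,frameRate,nFrames,modulationPeriod see
#'   \linkS4class{SceneSpec}.
#' @param driftVelocity c(x, y) px/frame.
#' @param background,sensor noise model lists (see
#'   \linkS4class{SceneSpec}).
#' @param renderWindow local render window side, px.
#' @param seed integer seed.
#' @return A \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(fov = c(128L, 128L), objects = list(), pixelPitch = 1.67,
                      wavelength = 0.65, frameRate = 26.7, nFrames = 120L,
                      modulationPeriod = 1, driftVelocity = c(0.05, 0),
                      background = list(speckleAmplitude = 0.08, grain = 3),
                      sensor = list(bitDepth = 10L, gain = 260, readNoise = 1.5,
                                    shotNoise = TRUE),
                      renderWindow = 64L, seed = 1L) {
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    if (o$kind == "random_walker" && is.na(o$motion$seed)) {
      objects[[i]]$motion$seed <- as.integer((seed * 7919 + i * 104729) %% 2147483647)
    }
  }
  new("SceneSpec", fov = as.integer(fov), pixelPitch = pixelPitch,
      wavelength = wavelength, frameRate = frameRate,
      nFrames = as.integer(nFrames), modulationPeriod = modulationPeriod,
      objects = objects, driftVelocity = driftVelocity,
      background = background, sensor = sensor,
      renderWindow = as.integer(renderWindow), seed = as.integer(seed))
}

# Relaxed square-wave response s(t) in [-1, 1]: the drive switches sign
# every half period; the response relaxes exponentially (time constant tau)
# toward the current extreme. s(0) = +1 (extreme A); the drive then pulls
# toward -1 (extreme B) during the first half period.
.relaxedSquareWave <- function(t, period, tau, phaseOffset = 0) {
  t <- t + phaseOffset
  half <- period / 2
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    nHalf <- floor(ti / half)
    tIn <- ti - nHalf * half
    target <- if (nHalf %% 2 == 0) -1 else 1
    # state at the start of this half period after nHalf relaxations
    sStart <- 1
    if (nHalf > 0) {
      e <- exp(-half / tau)
      # closed form of the alternating recursion s_{k+1} = T_k + (s_k - T_k) e
      for (kk in seq_len(nHalf)) {
        targ <- if ((kk - 1) %% 2 == 0) -1 else 1
        sStart <- targ + (sStart - targ) * e
      }
    }
    out[i] <- target + (sStart - target) * exp(-tIn / tau)
  }
  out
}

#' Object pose over frames
#'
#' Evaluates the motion model of one object at the requested frame indices:
#' position offset (px) and pattern orientation (rad). Oscillating cells
#' and bead chains follow the relaxed square-wave drive at the scene's
#' modulation period; random walkers take seeded Brownian steps with
#' per-axis step variance 2 x diffusion; all objects share the global
#' scene drift.
#'
#' @param obj a \code{\link{simObject}}.
#' @param frames integer frame indices (1-based).
#' @param scene the \linkS4class{SceneSpec}.
#' @return data.frame with columns \code{frame, x, y, theta}.
#' @export
objectTrajectory <- function(obj, frames, scene) {
  stopifnot(all(frames >= 1), all(frames <= scene@nFrames))
  t <- (frames - 1) / scene@frameRate
  x <- rep(obj$x, length(frames)) + scene@driftVelocity[1] * (frames - 1)
  y <- rep(obj$y, length(frames)) + scene@driftVelocity[2] * (frames - 1)
  theta <- numeric(length(frames))
  m <- obj$motion
  if (obj$kind == "oscillating_cell") {
    s <- .relaxedSquareWave(t, scene@modulationPeriod, m$relaxTime, m$phaseOffset)
    theta <- s * m$rotAmplitude
    y <- y + s * m$oscOffsetPx
  } else if (obj$kind == "bead_chain") {
    s <- .relaxedSquareWave(t, scene@modulationPeriod, m$relaxTime, m$phaseOffset)
    theta <- s * m$swingAngle
  } else if (obj$kind == "random_walker") {
    seed <- if (is.na(m$seed)) 1L else m$seed
    nmax <- max(frames)
    old <- .Random.seed_backup_run(seed, function() {
      matrix(stats::rnorm(2 * (scene@nFrames - 1), 0, sqrt(2 * m$diffusion)),
             ncol = 2)
    })
    px <- c(0, cumsum(old[, 1]))
    py <- c(0, cumsum(old[, 2]))
    x <- x + px[frames]
    y <- y + py[frames]
  }
  data.frame(frame = frames, x = x, y = y, theta = theta)
}

# run fn under a local RNG seed without disturbing the caller's stream
.Random.seed_backup_run <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- fn()
  if (has) assign(".Random.seed", old, envir = globalenv())
  out
}

# Anti-aliased disk mask on a local grid (1 px soft edge).
.diskMask <- function(n, cx, cy, r) {
  d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`))
  pmin(pmax(r - d + 0.5, 0), 1)
}

# Complex transmittance patch (n x n) of an object at a given pose; the
# patch centre sits at (cx, cy) in local coordinates.
.objectPatch <- function(obj, n, cx, cy, theta, pitch) {
  att <- matrix(0, n, n)
  ph <- matrix(0, n, n)
  m <- obj$motion
  if (obj$kind == "oscillating_cell") {
    rCell <- obj$radius / pitch
    cell <- .diskMask(n, cx, cy, rCell)
    att <- att + obj$amplitude * cell
    ph <- ph + obj$phase * cell
    # asymmetric internal bead pattern, rotated by theta: rolling changes
    # the cell's appearance, not only its position. The pattern is
    # re-centred on the cell so the contrast centroid tracks the cell body.
    rBead <- m$beadRadius / pitch
    ang <- 2.399963 * seq_len(m$nBeads)    # golden-angle spacing: asymmetric
    rr <- rCell * (0.25 + 0.55 * seq_len(m$nBeads) / m$nBeads)
    ox <- rr * cos(ang + theta)
    oy <- rr * sin(ang + theta)
    ox <- ox - mean(ox)                    # keep the pattern centred: the
    oy <- oy - mean(oy)                    # roll changes appearance only
    for (j in seq_len(m$nBeads)) {
      att <- att + 0.85 * .diskMask(n, cx + ox[j], cy + oy[j], rBead)
    }
  } else if (obj$kind == "bead_chain") {
    rBead <- m$beadRadius / pitch
    spacing <- 2.1 * rBead
    for (j in seq_len(m$nBeads)) {
      off <- (j - (m$nBeads + 1) / 2) * spacing
      bx <- cx + off * cos(theta)
      by <- cy + off * sin(theta)
      bm <- .diskMask(n, bx, by, rBead)
      att <- att + 0.85 * bm
      ph <- ph + 0.3 * bm
    }
  } else {  # random_walker / static_particle: small debris particle
    bm <- .diskMask(n, cx, cy, obj$radius / pitch)
    att <- att + obj$amplitude * bm
    ph <- ph + obj$phase * bm
  }
  att <- pmin(att, 0.98)
  (1 - att) * exp(1i * ph) - 1   # scattered part of the transmittance
}

#' Render a hologram video from a scene
#'
#' Renders every frame of the scene as an in-line hologram: per object, the
#' complex transmittance patch at its current pose is forward-propagated
#' from its depth to the sensor plane (angular spectrum, local window) and
#' superposed on a unit reference wave together with a static (drifting)
#' background speckle field; the intensity is digitised with Poisson shot
#' noise and Gaussian read noise at the configured bit depth. Fully
#' deterministic for a fixed scene seed.
#'
#' @param scene a \linkS4class{SceneSpec}.
#' @return list with \code{video} (a \linkS4class{HologramVideo}),
#'   \code{truth} (data.frame: id, kind, x, y, z, snr, clipped -- positions
#'   are the undrifted object anchors) and \code{trajectories} (per-frame
#'   poses of every object).
#' @export
renderHologramVideo <- function(scene) {
  stopifnot(is(scene, "SceneSpec"))
  set.seed(scene@seed)
  nr <- scene@fov[1]; nc <- scene@fov[2]
  nf <- scene@nFrames
  w <- min(scene@renderWindow, min(nr, nc))
  pitch <- scene@pixelPitch
  lam <- scene@wavelength
  # static background speckle: band-limited complex Gaussian field
  bg <- scene@background
  noiseF <- matrix(complex(real = stats::rnorm(nr * nc),
                           imaginary = stats::rnorm(nr * nc)), nr, nc)
  sig <- 1 / (2 * pi * max(bg$grain, 0.5) * pitch)
  G <- exp(-outer(.fftfreq(nr, pitch)^2, .fftfreq(nc, pitch)^2, `+`) / (2 * sig^2))
  spk <- fft(fft(noiseF) * G, inverse = TRUE) / (nr * nc)
  if (bg$speckleAmplitude > 0) {
    spk <- spk * (bg$speckleAmplitude / sqrt(mean(Mod(spk)^2)))
  } else spk <- spk * 0
  spkF <- fft(spk)
  fy <- .fftfreq(nr, 1); fx <- .fftfreq(nc, 1)
  sn <- scene@sensor
  maxDN <- 2^sn$bitDepth - 1
  trajs <- lapply(scene@objects, objectTrajectory,
                  frames = seq_len(nf), scene = scene)
  frames <- array(0, c(nr, nc, nf))
  peakSig <- rep(0, length(scene@objects))
  clipped <- rep(FALSE, length(scene@objects))
  # modulated objects are rendered on the full grid so their full fringe
  # aperture (which carries the axial information) reaches the sensor;
  # small background debris keeps the cheap local window
  objWindow <- vapply(scene@objects, function(o)
    if (o$kind %in% c("oscillating_cell", "bead_chain")) min(nr, nc)
    else w, numeric(1))
  for (i in seq_len(nf)) {
    field <- matrix(1 + 0i, nr, nc)
    if (bg$speckleAmplitude > 0) {
      dx <- scene@driftVelocity[1] * (i - 1)
      dy <- scene@driftVelocity[2] * (i - 1)
      ramp <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
      field <- field + fft(spkF * ramp, inverse = TRUE) / (nr * nc)
    }
    for (k in seq_along(scene@objects)) {
      obj <- scene@objects[[k]]
      tr <- trajs[[k]][i, ]
      x0 <- round(tr$x); y0 <- round(tr$y)
      if (x0 < 1 || x0 > nc || y0 < 1 || y0 > nr) {
        clipped[k] <- TRUE
        next
      }
      wk <- objWindow[k]
      half <- wk %/% 2
      cx <- half + (tr$x - x0)   # subpixel-accurate centre in the window
      cy <- half + (tr$y - y0)
      s <- .objectPatch(obj, wk, cx, cy, tr$theta, pitch)
      sp <- .asPropagate(s, obj$z, pitch, lam, padFactor = 2)
      ys <- y0 - half + seq_len(wk) - 0L
      xs <- x0 - half + seq_len(wk) - 0L
      yv <- ys >= 1 & ys <= nr; xv <- xs >= 1 & xs <= nc
      field[ys[yv], xs[xv]] <- field[ys[yv], xs[xv]] + sp[yv, xv]
      if (i == 1) peakSig[k] <- 2 * max(Mod(sp))
    }
    I <- Mod(field)^2
    e <- sn$gain * I
    if (isTRUE(sn$shotNoise)) {
      e <- stats::rpois(length(e), lambda = as.vector(e))
      dim(e) <- c(nr, nc)
    }
    dn <- e + stats::rnorm(nr * nc, 0, sn$readNoise)
    frames[, , i] <- pmin(pmax(round(dn), 0), maxDN)
  }
  noiseSd <- sqrt(ifelse(isTRUE(sn$shotNoise), sn$gain, 0) + sn$readNoise^2)
  # anchor position expressed in the drift-corrected coordinate frame
  # (drift correction aligns content to the middle reference frame)
  refFrame <- ceiling(nf / 2)
  truth <- data.frame(
    id = seq_along(scene@objects),
    kind = vapply(scene@objects, `[[`, character(1), "kind"),
    x = vapply(scene@objects, `[[`, numeric(1), "x"),
    y = vapply(scene@objects, `[[`, numeric(1), "y"),
    xRef = vapply(scene@objects, `[[`, numeric(1), "x") +
      scene@driftVelocity[1] * (refFrame - 1),
    yRef = vapply(scene@objects, `[[`, numeric(1), "y") +
      scene@driftVelocity[2] * (refFrame - 1),
    z = vapply(scene@objects, `[[`, numeric(1), "z"),
    snr = peakSig * sn$gain / noiseSd,
    clipped = clipped)
  video <- hologramVideo(frames, scene@frameRate, pitch, lam,
                         scene@modulationPeriod)
  list(video = video, truth = truth, trajectories = trajs)
}

#' Benchmark scene: oscillating cells in a noisy background
#'
#' The default end-to-end test scene: a 256 x 256 px field of view at the
#' acquisition defaults containing \code{nCells} bead-conjugated
#' oscillating cells, \code{nWalkers} Brownian debris particles,
#' \code{nStatic} static particles, static background speckle and slow
#' horizontal drift. Cells are placed away from the border margin with a
#' minimum mutual separation; cell depths are uniform in 850..1150 um so
#' that the field of view subtends the full pixel-limited numerical
#' aperture of each cell's hologram (a prerequisite for fine axial
#' localisation); background debris spans a wider 800..2500 um range.
#'
#' @param seed scene seed.
#' @param nCells,nWalkers,nStatic object counts (defaults 6, 20, 10).
#' @param fov field-of-view side in px.
#' @return A \linkS4class{SceneSpec}.
#' @export
benchmarkScene <- function(seed = 1L, nCells = 6L, nWalkers = 20L,
                           nStatic = 10L, fov = 256L) {
  set.seed(seed)
  objs <- list()
  # cells far enough apart that no neighbour enters another's 40 x 40
  # focus-scoring window; rare cells are sparse in real screens
  margin <- 40; minSep <- 48
  pos <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pos) < nCells && tries < 5000) {
    tries <- tries + 1
    p <- stats::runif(2, margin, fov - margin)
    if (nrow(pos) == 0 || min(sqrt(rowSums(sweep(pos, 2, p)^2))) >= minSep)
      pos <- rbind(pos, p)
  }
  if (nrow(pos) < nCells) stop("could not place cells with the required separation")
  for (k in seq_len(nCells)) {
    objs[[length(objs) + 1L]] <- simObject("oscillating_cell",
      x = pos[k, 1], y = pos[k, 2], z = stats::runif(1, 850, 1150),
      radius = 7.5, amplitude = 0.6, phase = 1.0,
      motion = list(phaseOffset = stats::runif(1, 0, 0.05)))
  }
  for (k in seq_len(nWalkers)) {
    objs[[length(objs) + 1L]] <- simObject("random_walker",
      x = stats::runif(1, 8, fov - 8), y = stats::runif(1, 8, fov - 8),
      z = stats::runif(1, 800, 2500), radius = 1.6, amplitude = 0.5,
      phase = 0.5)
  }
  for (k in seq_len(nStatic)) {
    objs[[length(objs) + 1L]] <- simObject("static_particle",
      x = stats::runif(1, 8, fov - 8), y = stats::runif(1, 8, fov - 8),
      z = stats::runif(1, 800, 2500), radius = 2.0, amplitude = 0.5,
      phase = 0.5)
  }
  sceneSpec(fov = c(fov, fov), objects = objs, seed = seed)
}

#' Desk-scale scene template
#'
#' A reduced acquisition profile for single-CPU dataset generation: 96 px
#' field of view, 24 frames at 12 fps (12 frames per 1 s drive period) and
#' the same optics and noise model as the full-scale scene. Object depths
#' for this profile live in the shallow 500..900 um range matched to the
#' smaller field of view.
#'
#' @param seed scene seed.
#' @param objects object list.
#' @return A \linkS4class{SceneSpec}.
#' @export
deskScene <- function(seed = 1L, objects = list()) {
  sceneSpec(fov = c(96L, 96L), objects = objects, frameRate = 12,
            nFrames = 24L, renderWindow = 48L, seed = seed)
}

#' Desk-scale depth grid
#'
#' Four planes, 400 to 1000 um in 200 um steps, matched to the desk-scale
#' scene's shallow depth range (the small field of view only captures an
#' object's fringe aperture at shallow depths).
#' @return A \linkS4class{DepthGrid}.
#' @export
deskDepthGrid <- function() depthGrid(400, 1000, 200)
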