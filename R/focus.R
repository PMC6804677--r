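# Per-candidate axial localisation (coarse grid argmax of the windowed
# motion-contrast sum, then a fine 10 um re-search) and generation of the
# in-focus amplitude/phase video fed to the classifier.

# Window offsets around a centre pixel: -19..+20 at the default 40 px
# window, clipped to [1, n]. Asymmetric on purpose (even window size).
.windowIdx <- function(centre, n, window = c(-19L, 20L)) {
  i <- round(centre) + seq(window[1], window[2])
  i[i >= 1 & i <= n]
}

#' Coarse autofocusing on the contrast volume
#'
#' Selects the depth-grid plane maximising the sum of the motion contrast
#' over a 40 x 40 px window (offsets -19..+20, i.e. 66.8 um x 66.8 um at
#' the default pitch) centred on the candidate's centroid:
#' \deqn{\hat z_k = \arg\max_{z_j} \sum_{x,y=-19}^{20} C(x_k + x, y_k + y; z_j)}
#' The window is clipped at the frame border (the sum runs over in-bounds
#' pixels only). Ties are broken deterministically toward the smallest z,
#' with a warning when the scores are entirely flat.
#'
#' @param volume a \linkS4class{MotionContrastVolume}.
#' @param candidate one row of a \code{\link{detectCandidates}} table, or
#'   any list with elements \code{x}, \code{y}.
#' @param window integer offsets \code{c(lo, hi)} of the scoring window.
#' @return list with \code{index} (grid plane), \code{z} (um) and
#'   \code{scores} (the per-plane windowed sums).
#' @export
autofocusCoarse <- function(volume, candidate, window = c(-19L, 20L)) {
  stopifnot(is(volume, "MotionContrastVolume"))
  d <- dim(volume@values)
  ys <- .windowIdx(candidate$y, d[1], window)
  xs <- .windowIdx(candidate$x, d[2], window)
  if (!length(ys) || !length(xs)) stop("candidate centroid outside frame bounds")
  scores <- vapply(seq_len(d[3]),
                   function(j) sum(volume@values[ys, xs, j]), numeric(1))
  if (diff(range(scores)) == 0)
    warning("degenerate focus scores (all equal); returning the smallest z")
  j <- which.max(scores)  # first maximum = smallest z on ties
  list(index = j, z = volume@grid@z[j], scores = scores)
}

# Crop a region x region window centred on (x, y) out of each frame,
# filling out-of-bounds pixels with the frame mean. Offsets follow the
# even-window convention -(region/2 - 1) .. region/2.
.cropStack <- function(frames, x, y, region, fill = NULL) {
  d <- dim(frames)
  off <- seq(-(region %/% 2 - 1L), region %/% 2)
  ys <- round(y) + off
  xs <- round(x) + off
  yv <- ys >= 1 & ys <= d[1]
  xv <- xs >= 1 & xs <= d[2]
  out <- array(0, c(region, region, d[3]))
  for (i in seq_len(d[3])) {
    f <- if (is.null(fill)) mean(frames[, , i]) else fill
    m <- matrix(f, region, region)
    m[yv, xv] <- frames[ys[yv], xs[xv], i]
    out[, , i] <- m
  }
  out
}

#' Fine autofocusing around the coarse depth
#'
#' Re-evaluates the windowed motion-contrast criterion on a fine axial grid
#' (default 10 um steps over +/- 100 um, one coarse step) around the coarse
#' depth, recomputing the filtered back-propagation and the contrast
#' statistic within a local neighbourhood of the candidate only. The
#' neighbourhood must subtend the hologram's captured numerical aperture
#' (roughly 0.2 z at the pixel-limited aperture) or it, not the optics,
#' caps the axial resolution; the default 192 px covers depths up to
#' about 1500 um at full aperture. The fine grid is clamped to the coarse
#' grid's range. Returns the coarse depth unchanged (with a warning) when
#' the fine scores are flat.
#'
#' @param video the drift-corrected \linkS4class{HologramVideo}.
#' @param candidate list/row with centroid \code{x}, \code{y}.
#' @param zCoarse coarse focus depth in um.
#' @param fineStep fine grid step in um (default 10).
#' @param fineHalfspan half-span of the fine search in um (default 100).
#' @param spec a \linkS4class{FilterSpec}.
#' @param N even frames per period; default \code{framesPerPeriod(video)}.
#' @param region local neighbourhood side in px (default 192).
#' @param window scoring-window offsets. The fine stage defaults to a
#'   16 x 16 px window (offsets -7..+8) matched to the candidate core: the
#'   full 40 x 40 coarse window integrates fringe clutter from neighbouring
#'   objects, whose own focus depths then compete with the candidate's.
#' @param padFactor propagation zero-padding factor.
#' @param zRange allowed depth range (defaults to the default depth grid's
#'   range); the fine grid is clamped into it with a warning.
#' @param differences amplitude-image (\code{"magnitude"}, default) or
#'   complex-field differences; see \code{\link{cmaContrast}}.
#' @return list with \code{z} (refined depth, um), \code{zGrid} and
#'   \code{scores}.
#' @export
autofocusRefine <- function(video, candidate, zCoarse, fineStep = 10,
                            fineHalfspan = 100, spec = filterSpec(),
                            N = framesPerPeriod(video), region = 192L,
                            window = c(-7L, 8L), padFactor = 1,
                            zRange = NULL,
                            differences = c("magnitude", "complex")) {
  differences <- match.arg(differences)
  stopifnot(is(video, "HologramVideo"))
  if (is.null(zRange)) zRange <- range(zValues(depthGrid()))
  zg <- seq(zCoarse - fineHalfspan, zCoarse + fineHalfspan, by = fineStep)
  if (any(zg < zRange[1] | zg > zRange[2])) {
    warning("fine grid clamped to the coarse grid range")
    zg <- zg[zg >= zRange[1] & zg <= zRange[2]]
  }
  nf <- nFrames(video)
  .checkCmaN(N, nf)
  crop <- .cropStack(video@frames, candidate$x, candidate$y, region)
  # spectra of the padded crops, shared across fine depths
  specs <- vector("list", nf)
  cr <- NULL
  for (i in seq_len(nf)) {
    mp <- .padField(crop[, , i] + 0i, padFactor)
    if (is.null(cr)) cr <- attr(mp, "crop")
    specs[[i]] <- fft(mp)
  }
  np <- region * padFactor
  fuse <- padFactor == 1
  G <- if (fuse) .hpTransfer(np, np, video@pixelPitch, spec@cutoff)
  # centroid position inside the crop
  cx <- region %/% 2  # centre pixel of the even window convention
  cy <- region %/% 2
  ys <- .windowIdx(cy, region, window)
  xs <- .windowIdx(cx, region, window)
  B <- array(0 + 0i, c(region, region, nf))
  scoreAt <- function(zs) {
    vapply(zs, function(z) {
      H <- .asTransfer(np, np, video@pixelPitch, video@wavelength, -z)
      if (fuse) H <- H * G
      for (i in seq_len(nf)) {
        p <- .cropField(fft(specs[[i]] * H, inverse = TRUE) / np^2, cr)
        B[, , i] <<- if (fuse) p else .hpApply(p, video@pixelPitch, spec@cutoff)
      }
      C <- .cmaPlanes(if (differences == "magnitude") Mod(B) else B, N)
      sum(C[ys, xs])
    }, numeric(1))
  }
  scores <- scoreAt(zg)
  if (diff(range(scores)) == 0) {
    warning("flat fine focus scores; keeping the coarse depth")
    return(list(z = zCoarse, zGrid = zg, scores = scores))
  }
  # The genuine focus peak is narrow (the depth of focus of the captured
  # aperture, tens of um) while fringe clutter from neighbouring objects
  # varies slowly over the search span; detrending with a running median
  # isolates the narrow peak before the argmax.
  sel <- scores
  if (length(zg) >= 15) {
    k <- min(11L, 2L * (length(zg) %/% 4L) + 1L)
    sel <- scores - stats::runmed(scores, k, endrule = "median")
    sel <- stats::filter(sel, rep(1 / 3, 3))      # 3-point mean vs spikes
    # the detrend is unreliable in the half-window at either end
    edge <- k %/% 2L
    sel[c(seq_len(edge), length(sel) + 1 - seq_len(edge))] <- -Inf
    sel[is.na(sel)] <- -Inf
  }
  list(z = zg[which.max(sel)], zGrid = zg, scores = scores,
       detrended = as.numeric(sel))
}

#' Extract the in-focus amplitude/phase video of a candidate
#'
#' Back-propagates every frame of the drift-corrected hologram sequence to
#' the candidate's refined focus plane (high-pass-filtered angular-spectrum
#' reconstruction of the full field of view), crops a window centred on the
#' centroid (zero-padded where it overhangs the frame), and emits a
#' two-channel video: amplitude (field magnitude) and phase (field
#' argument, in (-pi, pi], not unwrapped). The amplitude channel is
#' normalised per candidate to unit 99th percentile so the classifier is
#' decoupled from illumination brightness.
#'
#' @param video the drift-corrected \linkS4class{HologramVideo}.
#' @param candidate list/row with centroid \code{x}, \code{y}.
#' @param zRefined focus depth in um.
#' @param crop crop side in pixels (default 64).
#' @param spec a \linkS4class{FilterSpec}.
#' @param padFactor propagation zero-padding factor.
#' @param normalize normalise the amplitude channel (default TRUE).
#' @param id candidate id stored in the result.
#' @return A \linkS4class{CandidateVideo} with values
#'   2 x nFrames x crop x crop.
#' @export
extractCandidateVideo <- function(video, candidate, zRefined, crop = 64L,
                                  spec = filterSpec(), padFactor = 1,
                                  normalize = TRUE, id = 1L) {
  stopifnot(is(video, "HologramVideo"))
  d <- dim(video@frames)
  x0 <- round(candidate$x); y0 <- round(candidate$y)
  if (x0 < 1 || x0 > d[2] || y0 < 1 || y0 > d[1])
    stop("candidate centroid outside frame bounds")
  nf <- nFrames(video)
  off <- seq(-(crop %/% 2 - 1L), crop %/% 2)
  ys <- y0 + off; xs <- x0 + off
  yv <- ys >= 1 & ys <= d[1]; xv <- xs >= 1 & xs <= d[2]
  vals <- array(0, c(2, nf, crop, crop))
  fuse <- padFactor == 1
  HG <- if (fuse) {
    .asTransfer(d[1], d[2], video@pixelPitch, video@wavelength, -zRefined) *
      .hpTransfer(d[1], d[2], video@pixelPitch, spec@cutoff)
  }
  for (i in seq_len(nf)) {
    B <- if (fuse) {
      fft(fft(video@frames[, , i] + 0i) * HG, inverse = TRUE) / (d[1] * d[2])
    } else .hpApply(
      .asPropagate(video@frames[, , i] + 0i, -zRefined, video@pixelPitch,
                   video@wavelength, padFactor),
      video@pixelPitch, spec@cutoff)
    amp <- ph <- matrix(0, crop, crop)
    sub <- B[ys[yv], xs[xv], drop = FALSE]
    amp[yv, xv] <- Mod(sub)
    ph[yv, xv] <- Arg(sub)
    vals[1, i, , ] <- amp
    vals[2, i, , ] <- ph
  }
  if (normalize) {
    q <- stats::quantile(vals[1, , , ], 0.99, names = FALSE)
    if (q > 0) vals[1, , , ] <- vals[1, , , ] / q
  }
  new("CandidateVideo", values = vals, candidateId = as.integer(id),
      zRefined = zRefined, frameRate = video@frameRate)
}
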