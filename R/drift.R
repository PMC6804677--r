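# Phase-correlation drift estimation and bilinear drift removal.
#
# The sample fluid drifts slowly and almost purely translationally during an
# acquisition; each frame's shift relative to a reference frame (the middle
# frame by default) is estimated by phase correlation with subpixel
# refinement, and removed by bilinear resampling. By default only the
# horizontal (x) axis is corrected: the vertical axis carries the
# magnetically driven motion that the pipeline must preserve.

# Integer-peak phase correlation followed by locally upsampled DFT
# evaluation of the correlation surface (matrix-multiply DFT), giving
# roughly 1/usfac pixel resolution.
.phaseCorrelate <- function(ref, frame, usfac = 20L) {
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- fft(ref); Ff <- fft(frame)
  R <- Ff * Conj(Fr)
  mag <- Mod(R)
  nz <- mag > max(mag) * 1e-12
  if (sum(nz) < 2) return(list(shift = c(0, 0), degenerate = TRUE))
  R[nz] <- R[nz] / mag[nz]
  R[!nz] <- 0
  r <- Re(fft(R, inverse = TRUE)) / (nr * nc)
  p <- which(r == max(r), arr.ind = TRUE)[1, ]
  d <- c(p[1] - 1, p[2] - 1)
  if (d[1] > nr / 2) d[1] <- d[1] - nr
  if (d[2] > nc / 2) d[2] <- d[2] - nc
  # refine on a +/- 1.5 px window at 1/usfac resolution
  off <- seq(-1.5, 1.5, by = 1 / usfac)
  ky <- c(seq(0L, floor((nr - 1) / 2)), seq(-floor(nr / 2), -1L))
  kx <- c(seq(0L, floor((nc - 1) / 2)), seq(-floor(nc / 2), -1L))
  Ky <- exp(2i * pi * outer(d[1] + off, ky) / nr)
  Kx <- exp(2i * pi * outer(kx, d[2] + off) / nc)
  rf <- Re(Ky %*% R %*% Kx)
  pf <- which(rf == max(rf), arr.ind = TRUE)[1, ]
  list(shift = c(d[1] + off[pf[1]], d[2] + off[pf[2]]), degenerate = FALSE)
}

#' Estimate per-frame translational drift by phase correlation
#'
#' Estimates the lateral translation of every frame relative to a reference
#' frame (default: the middle frame) using the phase correlation method, with
#' subpixel refinement by local upsampling of the correlation peak
#' (resolution about 1/20 px). The reference frame's shift is exactly (0, 0).
#'
#' @param video a \linkS4class{HologramVideo}.
#' @param referenceIndex reference frame index; defaults to the middle frame.
#' @param usfac upsampling factor of the subpixel refinement.
#' @return data.frame with columns \code{frame}, \code{dx}, \code{dy}: the
#'   estimated shift of each frame's content relative to the reference
#'   (x = columns, y = rows).
#' @export
estimateDrift <- function(video, referenceIndex = NULL, usfac = 20L) {
  stopifnot(is(video, "HologramVideo"))
  nf <- nFrames(video)
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(referenceIndex)) referenceIndex <- ceiling(nf / 2)
  ref <- video@frames[, , referenceIndex]
  if (stats::sd(ref) == 0)
    warning("reference frame is constant: drift estimation is degenerate")
  dx <- dy <- numeric(nf)
  degen <- FALSE
  for (i in seq_len(nf)) {
    if (i == referenceIndex) next
    pc <- .phaseCorrelate(ref, video@frames[, , i], usfac)
    if (pc$degenerate) degen <- TRUE
    dy[i] <- pc$shift[1]
    dx[i] <- pc$shift[2]
  }
  if (degen) warning("degenerate (all-constant) frames: zero shifts returned")
  data.frame(frame = seq_len(nf), dx = dx, dy = dy)
}

# Integer translation with constant fill: out(y, x) = m(y + a, x + b).
.intShift <- function(m, a, b, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) + a; xs <- seq_len(nc) + b
  yv <- ys >= 1 & ys <= nr; xv <- xs >= 1 & xs <= nc
  if (any(yv) && any(xv)) out[yv, xv] <- m[ys[yv], xs[xv]]
  out
}

# Bilinear resampling of m at (y + sy, x + sx); out-of-bounds -> fill.
.bilinearShift <- function(m, sy, sx, fill) {
  a <- floor(sy); fy <- sy - a
  b <- floor(sx); fx <- sx - b
  if (fy == 0 && fx == 0) return(.intShift(m, a, b, fill))
  (1 - fy) * (1 - fx) * .intShift(m, a,     b,     fill) +
  (1 - fy) * fx       * .intShift(m, a,     b + 1, fill) +
  fy       * (1 - fx) * .intShift(m, a + 1, b,     fill) +
  fy       * fx       * .intShift(m, a + 1, b + 1, fill)
}

#' Remove estimated drift from a hologram video
#'
#' Resamples every frame by bilinear interpolation by the negated estimated
#' shift, restricted to the requested axes. The default corrects the
#' horizontal axis only (the tube axis along which the fluid drifts), leaving
#' the vertical magnetically driven motion untouched; pass
#' \code{axes = c("x", "y")} for full 2D correction. Out-of-bounds samples
#' are filled with the frame mean.
#'
#' @param video a \linkS4class{HologramVideo}.
#' @param shifts data.frame from \code{\link{estimateDrift}}.
#' @param axes subset of \code{c("x", "y")}; default \code{"x"}.
#' @return the drift-corrected \linkS4class{HologramVideo}
#'   (\code{driftCorrected} flag set).
#' @export
correctDrift <- function(video, shifts, axes = "x") {
  stopifnot(is(video, "HologramVideo"))
  nf <- nFrames(video)
  if (nrow(shifts) != nf) stop("shift count does not match frame count")
  axes <- match.arg(axes, c("x", "y"), several.ok = TRUE)
  frames <- video@frames
  for (i in seq_len(nf)) {
    sx <- if ("x" %in% axes) shifts$dx[i] else 0
    sy <- if ("y" %in% axes) shifts$dy[i] else 0
    if (sx == 0 && sy == 0) next
    frames[, , i] <- .bilinearShift(frames[, , i], sy, sx,
                                    fill = mean(frames[, , i]))
  }
  hologramVideo(frames, video@frameRate, video@pixelPitch, video@wavelength,
                video@modulationPeriod, driftCorrected = TRUE)
}
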