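# Periodic-motion contrast (computational motion analysis), maximum
# intensity projection and threshold-based candidate detection.

# CMA statistic over a sequence of complex planes stacked along the last
# dimension of a 3D array [rows, cols, nFrames]: mean over i of
# 0.5|B_i - B_{i+N/2}| + 0.5|B_{i+N/2} - B_{i+N}| - |B_i - B_{i+N}|.
.cmaPlanes <- function(B, N) {
  nf <- dim(B)[3]
  n2 <- N %/% 2L
  m <- nf - N
  i <- seq_len(m)
  Dh <- Mod(B[, , seq_len(nf - n2), drop = FALSE] -
            B[, , n2 + seq_len(nf - n2), drop = FALSE])
  Dw <- Mod(B[, , i, drop = FALSE] - B[, , N + i, drop = FALSE])
  acc <- 0.5 * rowSums(Dh[, , i, drop = FALSE], dims = 2) +
         0.5 * rowSums(Dh[, , n2 + i, drop = FALSE], dims = 2) -
         rowSums(Dw, dims = 2)
  acc / m
}

.checkCmaN <- function(N, nf) {
  if (N %% 2 != 0) stop("N (frames per period) must be even")
  if (N >= nf) stop("N must be smaller than the number of frames")
}

#' Periodic-motion contrast volume from per-frame reconstruction stacks
#'
#' Combines half-period and whole-period complex frame differences into the
#' motion contrast statistic
#' \deqn{C = \frac{1}{N_F - N}\sum_{i=1}^{N_F-N}\left(
#'   \tfrac12 |B_i - B_{i+N/2}| + \tfrac12 |B_{i+N/2} - B_{i+N}|
#'   - |B_i - B_{i+N}|\right)}
#' where N is the (even) number of frames per modulation period. Content
#' oscillating at the drive frequency makes the half-period terms large and
#' the whole-period term small (C > 0); static content cancels exactly
#' (C = 0); monotonic or diffusive motion gives C <= 0 by the triangle
#' inequality. Values may be negative and are not clipped.
#'
#' @param stacks per-frame reconstruction stacks: a list (one complex
#'   rows x cols x nz array per frame, as from
#'   \code{\link{filteredBackpropagate}}), or a 4D complex array
#'   rows x cols x nz x nFrames.
#' @param N even number of frames per modulation period.
#' @param grid optional \linkS4class{DepthGrid}; taken from the first
#'   stack's attribute when present.
#' @param differences \code{"magnitude"} (default) differences the
#'   reconstructed amplitude images |B|; \code{"complex"} differences the
#'   complex fields. Amplitude differencing is the convention used by the
#'   screening pipeline: defocused amplitude patterns of the two poses
#'   become alike, so the contrast decays away from the focus plane, which
#'   is what makes the windowed-sum autofocus criterion peak at focus.
#'   Complex differencing is exactly invariant under propagation (unitary)
#'   and therefore carries no depth selectivity.
#' @return A \linkS4class{MotionContrastVolume}.
#' @export
cmaContrast <- function(stacks, N, grid = NULL,
                        differences = c("magnitude", "complex")) {
  differences <- match.arg(differences)
  if (is.list(stacks)) {
    if (is.null(grid)) grid <- attr(stacks[[1]], "grid")
    d <- dim(stacks[[1]])
    if (!all(vapply(stacks, function(s) identical(dim(s), d), logical(1))))
      stop("all stacks must share the same shape")
    B <- array(0 + 0i, c(d, length(stacks)))
    for (i in seq_along(stacks)) B[, , , i] <- stacks[[i]]
  } else {
    B <- stacks
    if (is.null(grid)) grid <- attr(stacks, "grid")
  }
  stopifnot(length(dim(B)) == 4L)
  .checkCmaN(N, dim(B)[4])
  if (is.null(grid)) grid <- new("DepthGrid", z = seq_len(dim(B)[3]), step = 1)
  d <- dim(B)
  out <- array(0, d[1:3])
  for (j in seq_len(d[3])) {
    Bj <- B[, , j, , drop = FALSE]
    dim(Bj) <- d[c(1, 2, 4)]
    if (differences == "magnitude") Bj <- Mod(Bj)
    out[, , j] <- .cmaPlanes(Bj, N)
  }
  new("MotionContrastVolume", values = out, grid = grid)
}

#' Motion contrast volume straight from a hologram video
#'
#' Memory-efficient composition of \code{\link{filteredBackpropagate}} and
#' \code{\link{cmaContrast}}: the hologram spectrum of each frame is
#' computed once, then each depth plane is reconstructed, high-pass
#' filtered and reduced to its contrast plane before moving to the next
#' depth. Matches materialising all per-frame stacks and calling
#' \code{cmaContrast} to floating-point precision (with no padding the
#' high-pass is fused into the propagation multiply).
#'
#' @param video a drift-corrected \linkS4class{HologramVideo}.
#' @param grid a \linkS4class{DepthGrid}.
#' @param spec a \linkS4class{FilterSpec}.
#' @param N even frames per period; default \code{framesPerPeriod(video)}.
#' @param padFactor propagation zero-padding factor.
#' @param sqrtIntensity use the square root of the recorded intensity.
#' @param differences amplitude-image (\code{"magnitude"}, default) or
#'   complex-field differences; see \code{\link{cmaContrast}}.
#' @return A \linkS4class{MotionContrastVolume}.
#' @export
motionContrastVolume <- function(video, grid = depthGrid(), spec = filterSpec(),
                                 N = framesPerPeriod(video), padFactor = 1,
                                 sqrtIntensity = FALSE,
                                 differences = c("magnitude", "complex")) {
  differences <- match.arg(differences)
  stopifnot(is(video, "HologramVideo"), is(grid, "DepthGrid"))
  nf <- nFrames(video)
  .checkCmaN(N, nf)
  d <- dim(video@frames)
  # padded spectra, one per frame (shared across depths)
  specs <- vector("list", nf)
  crop <- NULL
  for (i in seq_len(nf)) {
    v <- video@frames[, , i]
    if (sqrtIntensity) v <- sqrt(pmax(v, 0))
    mp <- .padField(v + 0i, padFactor)
    if (is.null(crop)) crop <- attr(mp, "crop")
    specs[[i]] <- fft(mp)
  }
  np <- d[1:2] * padFactor
  fuse <- padFactor == 1   # unpadded: HP and propagation share one multiply
  G <- if (fuse) .hpTransfer(np[1], np[2], video@pixelPitch, spec@cutoff)
  out <- array(0, c(d[1], d[2], length(grid@z)))
  B <- array(0 + 0i, c(d[1], d[2], nf))
  for (j in seq_along(grid@z)) {
    H <- .asTransfer(np[1], np[2], video@pixelPitch, video@wavelength, -grid@z[j])
    if (fuse) H <- H * G
    for (i in seq_len(nf)) {
      p <- .cropField(fft(specs[[i]] * H, inverse = TRUE) / prod(np), crop)
      B[, , i] <- if (fuse) p else .hpApply(p, video@pixelPitch, spec@cutoff)
    }
    out[, , j] <- .cmaPlanes(if (differences == "magnitude") Mod(B) else B, N)
  }
  new("MotionContrastVolume", values = out, grid = grid)
}

#' Maximum intensity projection along depth
#'
#' Pointwise maximum of the contrast volume over the axial direction,
#' flattening the 3D contrast map into a 2D map for segmentation.
#'
#' @param volume a \linkS4class{MotionContrastVolume}.
#' @return numeric matrix (the projection map).
#' @export
projectMaxIntensity <- function(volume) {
  stopifnot(is(volume, "MotionContrastVolume"))
  v <- volume@values
  Reduce(pmax, lapply(seq_len(dim(v)[3]), function(j) v[, , j]))
}

# 8-connected component labelling of a logical matrix (iterative BFS).
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% nr + 1L
      cc <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
        k <- (c2 - 1L) * nr + rr
        if (mask[k] && lab[k] == 0L) {
          lab[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

#' Threshold-based candidate detection on a projection map
#'
#' Binarises the projection map, labels 8-connected components, discards
#' components smaller than \code{minArea}, and reports the intensity-weighted
#' centroid, area and peak contrast of each remaining component. Components
#' touching the border margin (default 32 px, half the candidate-video crop
#' size) are flagged rather than dropped. Coordinates are 1-based with
#' x = column and y = row, origin at the top-left pixel.
#'
#' @param map numeric matrix, typically from
#'   \code{\link{projectMaxIntensity}}.
#' @param threshold either a single absolute value, or a list
#'   \code{list(policy = "adaptive", kappa = 6)} meaning
#'   \code{mean(map) + kappa * sd(map)}.
#' @param minArea minimum component area in pixels (default 4).
#' @param borderMargin border margin in pixels (default 32).
#' @param minSeparation candidates closer than this to a stronger candidate
#'   are suppressed (non-maximum suppression; default 20 px, under half the
#'   candidate-video crop). An object's own diffraction sidelobes can
#'   otherwise cross the threshold as satellite components. Set 0 to
#'   disable.
#' @return data.frame with columns \code{id, x, y, area, peakScore, border,
#'   zCoarse, zRefined}; the applied threshold is attached as attribute
#'   \code{"threshold"}. May have zero rows.
#' @export
detectCandidates <- function(map, threshold = list(policy = "adaptive", kappa = 6),
                             minArea = 4L, borderMargin = 32L,
                             minSeparation = 20) {
  stopifnot(is.matrix(map), all(is.finite(map)))
  thr <- if (is.numeric(threshold) && length(threshold) == 1L) threshold
         else {
           stopifnot(identical(threshold$policy, "adaptive"))
           mean(map) + threshold$kappa * stats::sd(map)
         }
  mask <- map > thr
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), peakScore = numeric(0),
                      border = logical(0), zCoarse = numeric(0),
                      zRefined = numeric(0))
  attr(empty, "threshold") <- thr
  if (!any(mask)) return(empty)
  lb <- .label8(mask)
  rows <- list()
  nr <- nrow(map); nc <- ncol(map)
  for (k in seq_len(lb$n)) {
    px <- which(lb$labels == k, arr.ind = TRUE)
    if (nrow(px) < minArea) next
    w <- map[cbind(px[, 1], px[, 2])] - thr   # pedestal-free weights
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L,
      x = sum(w * px[, 2]) / sum(w),
      y = sum(w * px[, 1]) / sum(w),
      area = nrow(px),
      peakScore = max(w),
      border = any(px[, 1] <= borderMargin | px[, 1] > nr - borderMargin |
                   px[, 2] <= borderMargin | px[, 2] > nc - borderMargin),
      zCoarse = NA_real_, zRefined = NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out) > 1 && minSeparation > 0) {
    ord <- order(-out$peakScore)
    keep <- logical(nrow(out))
    for (i in ord) {
      kept <- which(keep)
      if (!length(kept) ||
          min(sqrt((out$x[kept] - out$x[i])^2 + (out$y[kept] - out$y[i])^2)) >=
            minSeparation)
        keep[i] <- TRUE
    }
    out <- out[keep, , drop = FALSE]
    out$id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- thr
  out
}
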