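# File interfaces: hologram videos as multi-page TIFF with a YAML metadata
# sidecar, candidate tables as CSV, models as RDS checkpoints.

#' Write a hologram video to multi-page TIFF + YAML metadata
#'
#' Frames are stored as 32-bit float TIFF pages scaled to [0, 1]; the scale
#' factor and the acquisition metadata go to a YAML sidecar (same path with
#' extension \code{.yml}).
#'
#' @param video a \linkS4class{HologramVideo}.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeHologramVideo <- function(video, path) {
  stopifnot(is(video, "HologramVideo"))
  scale <- max(1, max(video@frames))
  pages <- lapply(seq_len(nFrames(video)),
                  function(i) video@frames[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(frameRate = video@frameRate, pixelPitch = video@pixelPitch,
               wavelength = video@wavelength,
               modulationPeriod = video@modulationPeriod,
               driftCorrected = video@driftCorrected, scale = scale)
  yaml::write_yaml(meta, sub("\\.tiff?$", ".yml", path, ignore.case = TRUE))
  invisible(path)
}

#' Read a hologram video written by \code{\link{writeHologramVideo}}
#'
#' @param path TIFF path; the YAML sidecar is looked up next to it.
#' @return A \linkS4class{HologramVideo}.
#' @export
readHologramVideo <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sub("\\.tiff?$", ".yml", path, ignore.case = TRUE))
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * meta$scale
  hologramVideo(frames, meta$frameRate, meta$pixelPitch, meta$wavelength,
                meta$modulationPeriod, isTRUE(meta$driftCorrected))
}

#' Write / read a candidate table as CSV
#'
#' @param candidates data.frame from \code{\link{detectCandidates}} or
#'   \code{\link{screenSample}}.
#' @param path CSV path.
#' @return the path (write) or the data.frame (read).
#' @export
writeCandidates <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidates
#' @export
readCandidates <- function(path) {
  utils::read.csv(path)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint holds the full model list: configuration, parameters,
#' batch-norm state, training metrics and seed.
#'
#' @param model a \code{p3dModel}.
#' @param path checkpoint path.
#' @return the path (save) or the model (load).
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "p3dModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "p3dModel"))
  m
}

#' Write a 2D map (e.g. a projection map) as 32-bit float TIFF
#'
#' @param map numeric matrix.
#' @param path TIFF path.
#' @return the path, invisibly; the scale used is attached as attribute.
#' @export
writeMapTIFF <- function(map, path) {
  lo <- min(map); hi <- max(map)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((map - lo) / scale, path, bits.per.sample = 32L)
  invisible(structure(path, scale = scale, offset = lo))
}
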