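# End-to-end orchestration: drift correction -> filtered back-propagation
# -> motion contrast -> projection -> detection -> autofocus -> candidate
# videos -> classification -> counts and whole-blood concentration.

#' Screening configuration
#'
#' All tunables of the per-FOV screening chain plus the volume bookkeeping
#' used for concentration estimation. The per-FOV sample volume is the
#' field-of-view area times the capillary tube's inner depth (2 mm for the
#' 2 mm x 4 mm tube); the blood-equivalent volume scales the screened
#' volume by bloodVolume / finalSampleVolume (4 mL of whole blood is
#' enriched into 0.7 mL buffer + 2.5 mL methyl cellulose = 3.2 mL).
#'
#' @param grid \linkS4class{DepthGrid} for screening.
#' @param filter a \linkS4class{FilterSpec}.
#' @param axes drift-correction axes (default \code{"x"}).
#' @param kappa adaptive detection threshold (mean + kappa * sd).
#' @param minArea,borderMargin detection parameters (px).
#' @param crop candidate-video crop side (px).
#' @param refineRegion,fineStep,fineHalfspan fine autofocus parameters.
#' @param padFactor propagation zero-padding factor.
#' @param tubeDepth capillary inner depth (mm).
#' @param bloodVolume,finalSampleVolume preparation volumes (mL).
#' @return a \code{screeningConfig} list.
#' @export
screeningConfig <- function(grid = depthGrid(), filter = filterSpec(),
                            axes = "x", kappa = 6, minArea = 4L,
                            borderMargin = NULL, crop = 64L,
                            refineRegion = 192L, fineStep = 10,
                            fineHalfspan = 250, padFactor = 1,
                            tubeDepth = 2, bloodVolume = 4,
                            finalSampleVolume = 3.2) {
  if (is.null(borderMargin)) borderMargin <- as.integer(crop / 2)
  structure(list(grid = grid, filter = filter, axes = axes, kappa = kappa,
                 minArea = as.integer(minArea),
                 borderMargin = as.integer(borderMargin),
                 crop = as.integer(crop), refineRegion = as.integer(refineRegion),
                 fineStep = fineStep, fineHalfspan = fineHalfspan,
                 padFactor = padFactor, tubeDepth = tubeDepth,
                 bloodVolume = bloodVolume,
                 finalSampleVolume = finalSampleVolume),
            class = "screeningConfig")
}

#' Screen a single field of view
#'
#' Runs the full per-FOV chain and returns the candidate table (centroids,
#' areas, peak contrast, coarse and refined depths), the extracted
#' candidate videos and, when a model is supplied, the per-candidate class
#' probabilities and decisions.
#'
#' @param video a \linkS4class{HologramVideo} (raw; drift correction is
#'   applied here).
#' @param config a \code{\link{screeningConfig}}.
#' @param model optional trained \code{p3dModel}.
#' @param threshold a \code{DecisionThreshold} (or probability) used when
#'   \code{model} is given.
#' @return list: \code{candidates}, \code{videos}, \code{shifts},
#'   \code{detectionThreshold}.
#' @export
screenFov <- function(video, config = screeningConfig(), model = NULL,
                      threshold = 0.5) {
  stopifnot(is(video, "HologramVideo"))
  shifts <- estimateDrift(video)
  vid <- correctDrift(video, shifts, axes = config$axes)
  N <- framesPerPeriod(vid)
  vol <- motionContrastVolume(vid, config$grid, config$filter, N = N,
                              padFactor = config$padFactor)
  D <- projectMaxIntensity(vol)
  cands <- detectCandidates(D, threshold = list(policy = "adaptive",
                                                kappa = config$kappa),
                            minArea = config$minArea,
                            borderMargin = config$borderMargin)
  vids <- list()
  zr <- range(zValues(config$grid))
  if (nrow(cands)) {
    for (i in seq_len(nrow(cands))) {
      cf <- autofocusCoarse(vol, cands[i, ])
      cands$zCoarse[i] <- cf$z
      rf <- suppressWarnings(
        autofocusRefine(vid, cands[i, ], cf$z, fineStep = config$fineStep,
                        fineHalfspan = config$fineHalfspan,
                        spec = config$filter, N = N,
                        region = config$refineRegion,
                        padFactor = config$padFactor, zRange = zr))
      cands$zRefined[i] <- rf$z
      vids[[i]] <- extractCandidateVideo(vid, cands[i, ], rf$z,
                                         crop = config$crop,
                                         spec = config$filter,
                                         padFactor = config$padFactor, id = i)
    }
  }
  cands$probability <- rep(NA_real_, nrow(cands))
  cands$positive <- rep(NA, nrow(cands))
  if (!is.null(model) && nrow(cands)) {
    cl <- classifyVideos(model, vids, threshold)
    cands$probability <- cl$probability
    cands$positive <- cl$positive
  }
  list(candidates = cands, videos = vids, shifts = shifts,
       detectionThreshold = attr(cands, "threshold"))
}

#' Whole-blood concentration from a positive count
#'
#' The screened sample volume maps back to whole blood through the
#' preparation volumes: bloodEquivalentVolume = screenedVolume x
#' bloodVolume / finalSampleVolume (0.942 mL screened with a 4 mL -> 3.2 mL
#' preparation is equivalent to 1.1775 mL of whole blood); the
#' concentration is count / bloodEquivalentVolume.
#'
#' @param count number of classified positives.
#' @param screenedVolume imaged sample volume (mL).
#' @param bloodVolume whole-blood input volume (mL).
#' @param finalSampleVolume post-enrichment sample volume (mL).
#' @return list with \code{bloodEquivalentVolume} (mL) and
#'   \code{concentration} (cells/mL whole blood).
#' @export
estimateConcentration <- function(count, screenedVolume, bloodVolume = 4,
                                  finalSampleVolume = 3.2) {
  if (screenedVolume <= 0 || bloodVolume <= 0 || finalSampleVolume <= 0)
    stop("volumes must be positive")
  v <- screenedVolume * bloodVolume / finalSampleVolume
  list(bloodEquivalentVolume = v, concentration = count / v)
}

#' Screen a multi-FOV sample and estimate the concentration
#'
#' Applies \code{\link{screenFov}} to every field of view; a FOV failing
#' any stage is logged and skipped (the run fails only if every FOV fails).
#' Counts classified positives (or, with no model, non-border candidates),
#' accumulates the screened volume from the FOV geometry and converts to a
#' whole-blood concentration.
#'
#' @param videos list of \linkS4class{HologramVideo}, one per FOV.
#' @param config a \code{\link{screeningConfig}}.
#' @param model optional trained \code{p3dModel}.
#' @param threshold decision threshold for positives.
#' @return A \linkS4class{ScreeningResult}.
#' @export
screenSample <- function(videos, config = screeningConfig(), model = NULL,
                         threshold = 0.5) {
  stopifnot(is.list(videos), length(videos) >= 1)
  rows <- list(); failed <- integer(0); stageCounts <- list()
  screenedVolume <- 0
  for (f in seq_along(videos)) {
    res <- tryCatch(screenFov(videos[[f]], config, model, threshold),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("FOV %d failed and was skipped: %s", f, conditionMessage(res)))
      failed <- c(failed, f)
      next
    }
    d <- dim(videos[[f]]@frames)
    screenedVolume <- screenedVolume +
      (d[1] * videos[[f]]@pixelPitch / 1000) *
      (d[2] * videos[[f]]@pixelPitch / 1000) * config$tubeDepth / 1000
    cc <- res$candidates
    if (nrow(cc)) cc <- cbind(fov = f, cc) else
      cc <- cbind(fov = integer(0), cc)
    rows[[length(rows) + 1L]] <- cc
    stageCounts[[length(stageCounts) + 1L]] <-
      list(fov = f, detected = nrow(res$candidates),
           positive = if (is.null(model)) NA_integer_
                      else sum(res$candidates$positive, na.rm = TRUE))
  }
  if (length(failed) == length(videos)) stop("all FOVs failed")
  cands <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fov = integer(0), id = integer(0), x = numeric(0), y = numeric(0),
               area = integer(0), peakScore = numeric(0), border = logical(0),
               zCoarse = numeric(0), zRefined = numeric(0),
               probability = numeric(0), positive = logical(0))
  rownames(cands) <- NULL
  positives <- if (is.null(model)) sum(!cands$border)
               else sum(cands$positive, na.rm = TRUE)
  est <- estimateConcentration(positives, screenedVolume,
                               config$bloodVolume, config$finalSampleVolume)
  new("ScreeningResult", candidates = cands,
      positiveCount = as.integer(positives),
      screenedVolume = screenedVolume,
      bloodEquivalentVolume = est$bloodEquivalentVolume,
      concentration = est$concentration,
      metadata = list(nFov = length(videos), failedFov = failed,
                      stageCounts = stageCounts,
                      classified = !is.null(model),
                      threshold = if (inherits(threshold, "DecisionThreshold"))
                                    threshold$value else threshold,
                      config = config[setdiff(names(config),
                                              c("grid", "filter"))]))
}

#' Human-readable and machine-readable screening report
#'
#' @param result a \linkS4class{ScreeningResult}.
#' @param format \code{"text"} or \code{"json"}.
#' @param file optional path to write to.
#' @return the report record (list) invisibly for \code{"json"}, or the
#'   text lines for \code{"text"}.
#' @export
screeningReport <- function(result, format = c("text", "json"), file = NULL) {
  stopifnot(is(result, "ScreeningResult"))
  format <- match.arg(format)
  record <- list(
    positive_count = result@positiveCount,
    screened_volume_ml = result@screenedVolume,
    blood_equivalent_volume_ml = result@bloodEquivalentVolume,
    concentration_per_ml = result@concentration,
    n_candidates = nrow(result@candidates),
    candidates = result@candidates,
    metadata = result@metadata)
  if (format == "json") {
    js <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(file)) writeLines(js, file)
    return(invisible(record))
  }
  lines <- c(
    "Screening summary",
    sprintf("  fields of view : %d (%d failed)", result@metadata$nFov,
            length(result@metadata$failedFov)),
    sprintf("  candidates     : %d", nrow(result@candidates)),
    sprintf("  positives      : %d", result@positiveCount),
    sprintf("  screened volume: %.4g mL (%.4g mL whole-blood equivalent)",
            result@screenedVolume, result@bloodEquivalentVolume),
    sprintf("  concentration  : %.4g cells/mL whole blood", result@concentration))
  if (!is.null(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}

#' Rebuild a ScreeningResult from a JSON report
#'
#' @param file path to a JSON report written by \code{\link{screeningReport}}.
#' @return A \linkS4class{ScreeningResult}.
#' @export
loadScreeningResult <- function(file) {
  rec <- jsonlite::fromJSON(file)
  cands <- as.data.frame(rec$candidates)
  if (length(cands) == 0 || nrow(cands) == 0)
    cands <- data.frame(fov = integer(0), id = integer(0), x = numeric(0),
                        y = numeric(0), area = integer(0), peakScore = numeric(0),
                        border = logical(0), zCoarse = numeric(0),
                        zRefined = numeric(0), probability = numeric(0),
                        positive = logical(0))
  new("ScreeningResult", candidates = cands,
      positiveCount = as.integer(rec$positive_count),
      screenedVolume = rec$screened_volume_ml,
      bloodEquivalentVolume = rec$blood_equivalent_volume_ml,
      concentration = rec$concentration_per_ml,
      metadata = as.list(rec$metadata))
}
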