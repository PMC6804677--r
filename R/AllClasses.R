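#' @import methods
NULL

#' Complex optical field on a regular pixel grid
#'
#' A scalar complex field sampled on the sensor grid, together with the
#' physical metadata needed for free-space propagation: the pixel pitch and
#' the illumination wavelength (both in micrometres).
#'
#' @slot values complex matrix; rows index y (top-left origin), columns x.
#' @slot pixelPitch sampling pitch in um.
#' @slot wavelength illumination wavelength in um.
#' @export
setClass("ComplexField",
  representation(values = "matrix", pixelPitch = "numeric", wavelength = "numeric"))

setValidity("ComplexField", function(object) {
  msg <- NULL
  if (!is.complex(object@values) && !is.numeric(object@values))
    msg <- c(msg, "values must be a numeric or complex matrix")
  if (!all(is.finite(Re(object@values))) || !all(is.finite(Im(object@values))))
    msg <- c(msg, "field values must be finite")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  if (length(object@wavelength) != 1L || object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ComplexField
#'
#' @param values numeric or complex matrix (rows = y, columns = x).
#' @param pixelPitch pixel pitch in um.
#' @param wavelength wavelength in um.
#' @return A \linkS4class{ComplexField}.
#' @examples
#' f <- complexField(matrix(1 + 0i, 8, 8), pixelPitch = 1.67, wavelength = 0.65)
#' @export
complexField <- function(values, pixelPitch, wavelength) {
  if (is.numeric(values)) storage.mode(values) <- "complex"
  new("ComplexField", values = values, pixelPitch = pixelPitch,
      wavelength = wavelength)
}

#' Axial depth grid for volumetric back-propagation
#'
#' Ordered propagation distances covering the sample depth. The default grid
#' spans 800 um to 5000 um in 100 um steps (43 planes), which covers the full
#' inner depth of the sample tube above the sensor.
#'
#' @slot z strictly increasing propagation distances in um.
#' @slot step nominal grid step in um.
#' @export
setClass("DepthGrid", representation(z = "numeric", step = "numeric"))

setValidity("DepthGrid", function(object) {
  msg <- NULL
  if (length(object@z) < 1L) msg <- c(msg, "depth grid must be non-empty")
  if (any(diff(object@z) <= 0)) msg <- c(msg, "z must be strictly increasing")
  if (any(!is.finite(object@z))) msg <- c(msg, "z must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @param zmin,zmax grid limits in um.
#' @param step grid step in um.
#' @return A \linkS4class{DepthGrid}.
#' @examples
#' length(zValues(depthGrid()))  # 43
#' @rdname DepthGrid-class
#' @export
depthGrid <- function(zmin = 800, zmax = 5000, step = 100) {
  new("DepthGrid", z = seq(zmin, zmax, by = step), step = step)
}

#' @param object,x a \code{DepthGrid}.
#' @rdname DepthGrid-class
#' @export
zValues <- function(x) x@z

#' Spatial frequency-domain filter specification
#'
#' Transfer-function description of the spatial filter applied after every
#' back-propagation. The only implemented kind is a radially symmetric
#' Gaussian high-pass, \eqn{G(f) = 1 - \exp(-f^2 / (2\sigma_f^2))}, which is
#' exactly zero at zero frequency and approaches one well below the Nyquist
#' frequency for any practical cutoff. It removes the non-diffracted
#' background (DC and slowly varying shading) while passing object
#' diffraction detail.
#'
#' @slot kind filter kind; only \code{"gaussian_highpass"}.
#' @slot cutoff Gaussian width \eqn{\sigma_f} in cycles/um.
#' @export
setClass("FilterSpec", representation(kind = "character", cutoff = "numeric"))

setValidity("FilterSpec", function(object) {
  msg <- NULL
  if (!identical(object@kind, "gaussian_highpass"))
    msg <- c(msg, "kind must be 'gaussian_highpass'")
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) || object@cutoff < 0)
    msg <- c(msg, "cutoff must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' @param kind filter kind (only \code{"gaussian_highpass"}).
#' @param cutoff Gaussian width in cycles/um (default 0.1).
#' @return A \linkS4class{FilterSpec}.
#' @rdname FilterSpec-class
#' @export
filterSpec <- function(kind = "gaussian_highpass", cutoff = 0.1) {
  new("FilterSpec", kind = kind, cutoff = cutoff)
}

#' Time-resolved hologram video
#'
#' An in-line hologram sequence recorded (or simulated) while the sample is
#' magnetically modulated, with the acquisition metadata that the whole
#' pipeline needs.
#'
#' @slot frames numeric array rows x cols x nFrames.
#' @slot frameRate frames per second.
#' @slot pixelPitch pixel pitch in um.
#' @slot wavelength wavelength in um.
#' @slot modulationPeriod magnetic drive period in seconds.
#' @slot driftCorrected logical flag set by \code{\link{correctDrift}}.
#' @export
setClass("HologramVideo",
  representation(frames = "array", frameRate = "numeric", pixelPitch = "numeric",
                 wavelength = "numeric", modulationPeriod = "numeric",
                 driftCorrected = "logical"))

setValidity("HologramVideo", function(object) {
  msg <- NULL
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a rows x cols x nFrames array")
  if (any(!is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be positive")
  if (object@modulationPeriod <= 0) msg <- c(msg, "modulationPeriod must be positive")
  N <- 2 * round(object@frameRate * object@modulationPeriod / 2)
  if (!is.null(d) && length(d) == 3L && !(N > 0 && N < d[3]))
    msg <- c(msg, "frames per modulation period must satisfy 0 < N < nFrames")
  if (is.null(msg)) TRUE else msg
})

#' @param frames rows x cols x nFrames numeric array.
#' @param frameRate frames per second (default 26.7).
#' @param pixelPitch pixel pitch in um (default 1.67).
#' @param wavelength wavelength in um (default 0.65).
#' @param modulationPeriod drive period in s (default 1).
#' @param driftCorrected logical.
#' @return A \linkS4class{HologramVideo}.
#' @rdname HologramVideo-class
#' @export
hologramVideo <- function(frames, frameRate = 26.7, pixelPitch = 1.67,
                          wavelength = 0.65, modulationPeriod = 1,
                          driftCorrected = FALSE) {
  new("HologramVideo", frames = frames, frameRate = frameRate,
      pixelPitch = pixelPitch, wavelength = wavelength,
      modulationPeriod = modulationPeriod, driftCorrected = driftCorrected)
}

#' Number of frames spanning one modulation period
#'
#' The frame count N used by the periodic-motion contrast statistic. The
#' statistic needs N even (half-period differences), so the product
#' frameRate x modulationPeriod is rounded to the nearest even integer:
#' 26.7 fps x 1 s gives N = 26 (a mismatch of about 1.3% of a period).
#'
#' @param video a \linkS4class{HologramVideo}.
#' @return even integer N.
#' @export
framesPerPeriod <- function(video) {
  as.integer(2 * round(video@frameRate * video@modulationPeriod / 2))
}

#' @rdname HologramVideo-class
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' 3D periodic-motion contrast volume
#'
#' The contrast statistic C(x, y; z) evaluated over the depth grid: large
#' positive where the field oscillates at the magnetic drive frequency,
#' near zero for static content and negative for monotonic or diffusive
#' motion. Negative values are retained (the autofocus criterion sums raw
#' values); projection and thresholding ignore them naturally.
#'
#' @slot values rows x cols x nz numeric array.
#' @slot grid the \linkS4class{DepthGrid} the volume was computed on.
#' @export
setClass("MotionContrastVolume",
  representation(values = "array", grid = "DepthGrid"))

setValidity("MotionContrastVolume", function(object) {
  d <- dim(object@values)
  msg <- NULL
  if (length(d) != 3L) msg <- c(msg, "values must be rows x cols x nz")
  else if (d[3] != length(object@grid@z))
    msg <- c(msg, "third dimension must match the depth grid")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Per-candidate in-focus amplitude/phase video
#'
#' Two-channel video of a detected candidate, obtained by back-propagating
#' every drift-corrected frame to the candidate's refined focus plane and
#' cropping around its centroid. Channel 1 is amplitude (non-negative,
#' normalised per candidate to unit 99th percentile), channel 2 phase in
#' (-pi, pi]. The full-scale shape is 2 x 120 x 64 x 64.
#'
#' @slot values array channels(2) x frames x rows x cols.
#' @slot candidateId integer id of the source candidate.
#' @slot zRefined refined focus depth in um.
#' @slot frameRate frames per second.
#' @export
setClass("CandidateVideo",
  representation(values = "array", candidateId = "integer",
                 zRefined = "numeric", frameRate = "numeric"))

setValidity("CandidateVideo", function(object) {
  d <- dim(object@values)
  msg <- NULL
  if (length(d) != 4L || d[1] != 2L)
    msg <- c(msg, "values must be 2 x frames x rows x cols")
  else {
    if (min(object@values[1, , , ]) < 0)
      msg <- c(msg, "amplitude channel must be non-negative")
    ph <- object@values[2, , , ]
    if (min(ph) <= -pi - 1e-9 || max(ph) > pi + 1e-9)
      msg <- c(msg, "phase channel must lie in (-pi, pi]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Aggregated result of screening a sample
#'
#' @slot candidates data.frame with one row per candidate across all FOVs
#'   (fov, id, x, y, area, peakScore, border, zCoarse, zRefined,
#'   probability, positive).
#' @slot positiveCount number of classified positives.
#' @slot screenedVolume imaged sample volume in mL.
#' @slot bloodEquivalentVolume whole-blood-equivalent volume in mL.
#' @slot concentration positives per mL of whole blood.
#' @slot metadata run metadata (seeds, config, per-FOV stage counts).
#' @export
setClass("ScreeningResult",
  representation(candidates = "data.frame", positiveCount = "integer",
                 screenedVolume = "numeric", bloodEquivalentVolume = "numeric",
                 concentration = "numeric", metadata = "list"))

setValidity("ScreeningResult", function(object) {
  msg <- NULL
  if (object@screenedVolume <= 0 || object@bloodEquivalentVolume <= 0)
    msg <- c(msg, "volumes must be positive")
  expect <- object@positiveCount / object@bloodEquivalentVolume
  if (abs(object@concentration - expect) > 1e-9 * max(1, expect))
    msg <- c(msg, "concentration must equal positiveCount / bloodEquivalentVolume")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ComplexField", function(object) {
  d <- dim(object@values)
  cat(sprintf("ComplexField %d x %d | pitch %.3g um | lambda %.3g um\n",
              d[1], d[2], object@pixelPitch, object@wavelength))
})

setMethod("show", "DepthGrid", function(object) {
  cat(sprintf("DepthGrid: %d planes, %.6g..%.6g um (step %.6g um)\n",
              length(object@z), min(object@z), max(object@z), object@step))
})

setMethod("show", "HologramVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "HologramVideo %d x %d px, %d frames @ %.4g fps | pitch %.3g um | period %.3g s | drift-corrected: %s\n",
    d[1], d[2], d[3], object@frameRate, object@pixelPitch,
    object@modulationPeriod, object@driftCorrected))
})

setMethod("show", "MotionContrastVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("MotionContrastVolume %d x %d x %d planes (%.6g..%.6g um)\n",
              d[1], d[2], d[3], min(object@grid@z), max(object@grid@z)))
})

setMethod("show", "CandidateVideo", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "CandidateVideo id %d: 2 x %d x %d x %d @ %.4g fps, z = %.5g um\n",
    object@candidateId, d[2], d[3], d[4], object@frameRate, object@zRefined))
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf(
    "ScreeningResult: %d candidates, %d positive | %.4g mL screened (%.4g mL blood equiv.) | %.4g cells/mL\n",
    nrow(object@candidates), object@positiveCount, object@screenedVolume,
    object@bloodEquivalentVolume, object@concentration))
})

#' @rdname MotionContrastVolume-class
#' @param x a \code{MotionContrastVolume}, \code{CandidateVideo} or
#'   \code{ScreeningResult}.
#' @export
contrastValues <- function(x) x@values

#' @rdname CandidateVideo-class
#' @export
videoValues <- function(x) x@values

#' @rdname ScreeningResult-class
#' @export
candidateTable <- function(x) x@candidates
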