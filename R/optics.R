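# Scalar-diffraction engine: FFT-based angular-spectrum propagation with
# evanescent cut-off, Gaussian high-pass filtering, and the filtered
# back-propagation of a hologram frame over a depth grid.

# DFT sample frequencies in cycles per unit length (like numpy fftfreq).
.fftfreq <- function(n, d) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Angular-spectrum transfer function on an nr x nc grid for propagation by
# +z along the optical axis; evanescent components are zeroed.
.asTransfer <- function(nr, nc, pitch, wavelength, z) {
  fy <- .fftfreq(nr, pitch)
  fx <- .fftfreq(nc, pitch)
  arg <- 1 - outer((wavelength * fy)^2, (wavelength * fx)^2, `+`)
  H <- matrix(0 + 0i, nr, nc)
  prop <- arg > 0
  H[prop] <- exp(2i * pi * z / wavelength * sqrt(arg[prop]))
  H
}

.padField <- function(m, padFactor) {
  if (padFactor <= 1) return(m)
  d <- dim(m)
  out <- matrix(0 + 0i, d[1] * padFactor, d[2] * padFactor)
  r0 <- floor((d[1] * padFactor - d[1]) / 2)
  c0 <- floor((d[2] * padFactor - d[2]) / 2)
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- m
  attr(out, "crop") <- c(r0, c0, d[1], d[2])
  out
}

.cropField <- function(m, crop) {
  if (is.null(crop)) return(m)
  m[crop[1] + seq_len(crop[3]), crop[2] + seq_len(crop[4])]
}

# Core propagation of a complex matrix; padFactor >= 1 zero-pads to suppress
# wrap-around of the circular convolution, then crops back.
.asPropagate <- function(m, z, pitch, wavelength, padFactor = 2) {
  if (z == 0) return(m)
  mp <- .padField(m, padFactor)
  crop <- attr(mp, "crop")
  H <- .asTransfer(nrow(mp), ncol(mp), pitch, wavelength, z)
  out <- fft(fft(mp) * H, inverse = TRUE) / length(mp)
  .cropField(out, crop)
}

# Gaussian high-pass transfer G(f) = 1 - exp(-f^2 / (2 sigma^2)); sigma = 0
# degenerates to pure DC removal.
.hpTransfer <- function(nr, nc, pitch, cutoff) {
  f2 <- outer(.fftfreq(nr, pitch)^2, .fftfreq(nc, pitch)^2, `+`)
  if (cutoff == 0) {
    G <- matrix(1, nr, nc)
    G[1, 1] <- 0
    return(G)
  }
  1 - exp(-f2 / (2 * cutoff^2))
}

.hpApply <- function(m, pitch, cutoff) {
  G <- .hpTransfer(nrow(m), ncol(m), pitch, cutoff)
  fft(fft(m) * G, inverse = TRUE) / length(m)
}

#' Angular-spectrum free-space propagation
#'
#' Propagates a sampled complex field by a signed axial distance using the
#' angular spectrum method: the field's spatial-frequency spectrum is
#' multiplied by the exact free-space transfer function
#' \eqn{\exp(i 2\pi z / \lambda \sqrt{1 - (\lambda f_x)^2 - (\lambda f_y)^2})};
#' evanescent components (\eqn{(\lambda f_x)^2 + (\lambda f_y)^2 > 1}) are
#' zeroed. Positive distances propagate away from the sensor toward the
#' source; back-propagation toward the object plane uses negative distances.
#'
#' With \code{padFactor > 1} the field is zero-padded before the FFT to
#' suppress wrap-around and cropped back afterwards; padding makes the
#' operation non-unitary at the crop boundary, so analytic identities
#' (round trip, energy conservation) hold exactly only at
#' \code{padFactor = 1}, where propagation is a unitary circular convolution
#' on the propagating band.
#'
#' @param field a \linkS4class{ComplexField}.
#' @param distance signed propagation distance in um; 0 is the identity.
#' @param padFactor linear zero-padding factor (default 2).
#' @return the propagated \linkS4class{ComplexField} on the same grid.
#' @examples
#' f <- complexField(matrix(1 + 0i, 16, 16), 1.67, 0.65)
#' g <- angularSpectrumPropagate(f, 500, padFactor = 1)
#' max(abs(Mod(g@values) - 1))  # plane wave: magnitude preserved
#' @export
angularSpectrumPropagate <- function(field, distance, padFactor = 2) {
  stopifnot(is(field, "ComplexField"))
  if (!is.finite(distance)) stop("distance must be finite")
  if (field@wavelength >= 2 * field@pixelPitch)
    warning("wavelength >= 2 * pixelPitch: the grid undersamples the propagating band")
  out <- .asPropagate(field@values, distance, field@pixelPitch,
                      field@wavelength, padFactor)
  complexField(out, field@pixelPitch, field@wavelength)
}

#' Spatial high-pass filtering of a complex field
#'
#' Frequency-domain multiplication by the filter's transfer function. The
#' Gaussian high-pass removes the zero-frequency component exactly and
#' passes high frequencies essentially unchanged; it suppresses the
#' non-diffracted illumination background of an in-line hologram before
#' motion analysis.
#'
#' @param field a \linkS4class{ComplexField}.
#' @param spec a \linkS4class{FilterSpec}.
#' @return the filtered \linkS4class{ComplexField}.
#' @export
highPassFilter <- function(field, spec = filterSpec()) {
  stopifnot(is(field, "ComplexField"), is(spec, "FilterSpec"))
  out <- .hpApply(field@values, field@pixelPitch, spec@cutoff)
  complexField(out, field@pixelPitch, field@wavelength)
}

#' Filtered back-propagation of a hologram over a depth grid
#'
#' Computes, for every grid depth \eqn{z_j}, the high-pass-filtered
#' back-propagation of a drift-corrected hologram frame:
#' \eqn{B(z_j) = HP[P(A, -z_j)]}. The recorded intensity frame is used
#' directly as a real-valued field (standard practice for in-line holograms;
#' set \code{sqrtIntensity = TRUE} to use its square root instead). Each
#' returned plane is bit-identical to composing
#' \code{highPassFilter(angularSpectrumPropagate(frame, -z), spec)}.
#'
#' @param frame a \linkS4class{ComplexField} holding the (real-valued)
#'   hologram frame, or a numeric matrix plus \code{pixelPitch}/
#'   \code{wavelength}.
#' @param grid a \linkS4class{DepthGrid}.
#' @param spec a \linkS4class{FilterSpec}.
#' @param padFactor zero-padding factor for propagation.
#' @param sqrtIntensity take the square root of the frame first.
#' @param pixelPitch,wavelength metadata when \code{frame} is a matrix.
#' @return complex array rows x cols x nz, with the grid attached as
#'   attribute \code{"grid"}.
#' @export
filteredBackpropagate <- function(frame, grid = depthGrid(), spec = filterSpec(),
                                  padFactor = 2, sqrtIntensity = FALSE,
                                  pixelPitch = NULL, wavelength = NULL) {
  if (is.matrix(frame)) {
    stopifnot(!is.null(pixelPitch), !is.null(wavelength))
    frame <- complexField(frame, pixelPitch, wavelength)
  }
  stopifnot(is(frame, "ComplexField"), is(grid, "DepthGrid"))
  if (length(grid@z) == 0) stop("empty depth grid")
  v <- frame@values
  if (sqrtIntensity) v <- sqrt(pmax(Re(v), 0)) + 0i
  f <- complexField(v, frame@pixelPitch, frame@wavelength)
  out <- array(0 + 0i, c(nrow(v), ncol(v), length(grid@z)))
  for (j in seq_along(grid@z)) {
    p <- angularSpectrumPropagate(f, -grid@z[j], padFactor = padFactor)
    out[, , j] <- highPassFilter(p, spec)@values
  }
  attr(out, "grid") <- grid
  out
}

#' Physical extent of the autofocus window
#'
#' Side length in um of the square focus-scoring window (offsets -19..+20,
#' i.e. 40 pixels) at a given pixel pitch: 40 x 1.67 um = 66.8 um at the
#' default sensor pitch.
#'
#' @param pixelPitch pixel pitch in um.
#' @param windowPixels window side in pixels (default 40).
#' @return window side length in um.
#' @export
focusWindowExtent <- function(pixelPitch = 1.67, windowPixels = 40L) {
  windowPixels * pixelPitch
}
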