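---
title: "Computational methods of the holocyte screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational methods of the holocyte screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holocyte)
```

## The measurement

holocyte implements the computational side of a lensless cytometer for rare
cells in blood. Cells carrying a surface marker are bound to superparamagnetic
beads, magnetically enriched, embedded in a viscous medium inside a capillary
tube, and oscillated by two anti-phased electromagnets driven with a 1 s
square wave. A laser diode (650 nm) illuminates the tube from above and a
CMOS sensor (1.67 um pitch) ~1 mm below records in-line holograms at 26.7 fps,
120 frames per position. Everything downstream of the raw frames is what this
package provides: the bead-laden cells are found because they are the only
objects in the scene that move *periodically at the drive frequency*, and
they are told apart from oscillating bead clusters by a video classifier that
sees their spatio-temporal signature.

## Volumetric reconstruction

Each drift-corrected frame $A_i$ is treated directly as a real-valued field
(taking its square root is available as an option; for weak scatterers on a
unit background the two differ only in scaling) and numerically refocused to
every depth of a grid $z_j$ with the angular spectrum method, followed by a
spatial high-pass:

$$B_i(z_j) = HP\!\left[\mathcal{P}(A_i, -z_j)\right]$$

The default grid spans 800 to 5000 um in 100 um steps (43 planes), covering
the capillary's inner depth. The angular-spectrum transfer function is exact
scalar propagation; evanescent components are zeroed. The high-pass is a
radial Gaussian, $G(f) = 1 - e^{-f^2/2\sigma_f^2}$, with $\sigma_f = 0.1$
cycles/um by default. The cutoff matters more than it may appear: the
autofocus criterion below sums absolute contrast values over a fixed window,
and only content that *leaves* that window quickly under defocus can make
the criterion peak at the focus plane. Low-frequency object envelopes spread
at $\lambda f$ um per um of defocus -- a few per cent of the window per 100
um -- and with a permissive cutoff ($\sigma_f \approx 0.01$) they dominate
the sum and erase the focus peak entirely. At $\sigma_f = 0.1$ only fringe
content survives, which disperses at $\approx 0.1$--$0.2$ um/um and gives
the criterion its selectivity. The cutoff is configurable in `filterSpec()`.

Two propagation details are deliberate:

* The generic operator `angularSpectrumPropagate()` zero-pads by a linear
  factor 2 before the FFT (suppressing wrap-around) and crops back. The
  *screening* path (`motionContrastVolume()`, `autofocusRefine()`,
  `extractCandidateVideo()`) instead defaults to unpadded, periodic
  propagation: padding + cropping loses energy roughly in proportion to the
  propagation distance, which makes the noise floor of the contrast volume
  depth-dependent and buries the focus peak under a baseline trend. Periodic
  propagation is unitary, so the background statistics are exactly
  depth-invariant; the wrap-around content it admits is static in time and
  cancels identically in the frame-difference statistic below.
* When unpadded, the high-pass and the propagation act in the same discrete
  Fourier basis, so the pipeline fuses them into a single spectral multiply;
  this is mathematically identical to the explicit composition (which
  `filteredBackpropagate()` always performs) and halves the FFT count.

## Drift correction

The fluid drifts slowly and almost purely translationally. Each frame's
shift relative to the middle frame is estimated by phase correlation with
local upsampled-DFT refinement (~0.05 px resolution) and removed by bilinear
resampling -- by default along the horizontal (tube) axis only, because the
vertical axis carries the magnetically driven motion that must be preserved.

## Periodic-motion contrast

For every depth, half-period and whole-period frame differences combine into

$$C(z_j) = \frac{1}{N_F-N}\sum_{i=1}^{N_F-N}\Big(\tfrac12\big|B_i - B_{i+N/2}\big|
 + \tfrac12\big|B_{i+N/2} - B_{i+N}\big| - \big|B_i - B_{i+N}\big|\Big)$$

with $N$ the (even) number of frames per drive period; 26.7 fps over a 1 s
period gives $N = 26$ after rounding to the nearest even integer (a 1.3%
period mismatch). For drive-periodic content the whole-period term vanishes
and the half-period terms are large ($C>0$); static content cancels exactly;
monotonic or Brownian motion makes $C\le 0$ by the triangle inequality.

One representational choice deserves emphasis. If the differences are taken
between *complex* fields, propagation (a unitary operator) preserves the
total energy of every difference field, so the contrast volume carries no
depth information at all -- measured windowed sums are *minimised* near
focus, because spreading a fixed-energy field raises its $\ell_1$ norm
inside a window. Taking differences between reconstructed *amplitude images*
$|B_i|$ breaks this invariance: strongly defocused amplitude patterns of two
object poses become indistinguishable and their difference decays, so the
contrast concentrates at the focus plane. The package therefore defaults to
amplitude differences (`differences = "magnitude"`); the complex convention
is retained as an option and both satisfy the analytic identities (static
cancellation, half-period alternation, ramp) asserted in the tests.

A maximum intensity projection over depth flattens $C$ to a 2D map $D$,
which is thresholded (default: mean + 6 sd, configurable or absolute),
segmented into 8-connected components of at least 4 px, and reduced to
intensity-weighted centroids with pedestal-subtracted weights. Components
touching the border margin (half the crop size) are flagged; non-maximum
suppression within 20 px removes satellite blobs caused by an object's own
diffraction sidelobes crossing the threshold.

## Autofocusing

Per candidate the coarse depth maximises the windowed contrast sum

$$\hat z_k = \arg\max_{z_j}\ \sum_{x,y=-19}^{20} C(x_k+x,\, y_k+y;\, z_j)$$

over the grid -- a 40 x 40 px (66.8 um) window, kept exactly asymmetric as
defined. Refinement re-evaluates the same criterion on a 10 um grid within
+-250 um of the coarse depth, recomputing the reconstruction and contrast in
a local neighbourhood only (default 192 px) and scoring over a tighter
16 x 16 px window matched to the candidate core -- the full 40 x 40 window
integrates fringe clutter from neighbouring objects, whose own focus depths
otherwise compete with the candidate's. The neighbourhood size is a
physical constraint, not a convenience: the captured fringe aperture sets
the effective numerical aperture, and with it the depth of focus
$\lambda/\mathrm{NA}^2$. A 64 px neighbourhood at $z \approx 1$ mm caps the
axial resolution at hundreds of um; 192 px subtends the full pixel-limited
aperture (NA $\approx 0.2$, depth of focus $\approx 17$ um) for depths up to
about 1.5 mm. Because fringe clutter from neighbouring objects varies slowly
across the search span while the self-focus peak is depth-of-focus narrow,
the refined profile is detrended with a running median before the argmax.
Ties break deterministically toward the smallest depth; flat profiles return
the coarse depth with a warning.

Each candidate then yields a two-channel video: every frame refocused to the
refined depth, cropped (64 x 64 at full scale) around the centroid with
zero-padding at frame edges, amplitude = field magnitude normalised per
candidate to unit 99th percentile (decoupling the classifier from
illumination brightness), phase = field argument in $(-\pi,\pi]$, not
unwrapped.

## The video classifier

The classifier is a densely connected pseudo-3D CNN operating on
$2 \times 120 \times 64 \times 64$ videos. A plain $1\times7\times7$ spatial
convolution (stride 2) and a plain $9\times1\times1$ temporal convolution
(stride 3), both with same-style padding and 16 output channels, form the
stem. Five dense blocks follow; each maps $m_p$ to

$$m_{p+1} = \mathrm{Max}\big[\mathrm{Conv}_t(\mathrm{Conv}_s(m_p)\oplus m_p)
\oplus(\mathrm{Conv}_s(m_p)\oplus m_p)\big]$$

where $\mathrm{Conv}_s$/$\mathrm{Conv}_t$ are batch-norm, rectifier, then a
$1\times3\times3$ / $3\times1\times1$ convolution with growth rate $k = 8$
output channels, $\oplus$ concatenates channels, and Max is
$2\times2\times2$ stride-2 pooling -- so every block adds exactly $2k$
channels and halves every extent. Between blocks 2 and 3 an unpadded
$3\times1\times1$ convolution trims the temporal extent from 10 to 8 so that
time and space reach $1\times1\times1$ together: temporally
$120 \to 40 \to 20 \to 10 \to 8 \to 4 \to 2 \to 1$, spatially
$64 \to 32 \to 16 \to 8 \to 4 \to 2 \to 1$. The $2\times2\times2$ stride-2
pooling is the only choice that makes this arithmetic close. Dropout 0.5, a fully connected
layer and softmax produce the two class probabilities. Convolution kernels
initialise from a truncated normal (sd 0.05, clipped at 2 sd); the fully
connected layer initialises to zero.

Training uses Adam (full-scale defaults: learning rate 1e-4, batch 240,
~800 epochs) on cross-entropy with per-video augmentation by random
mirroring and 90/180/270-degree rotation (applied to whole videos, so
temporal coherence is preserved). Sensitivity and specificity on a held-out
validation set are logged per epoch. All layers, including the factored
convolutions (implemented in compiled code) are verified against numerical
gradients in the test suite.

Because the application is rare-cell counting, the operating point is not
the argmax: the decision threshold is raised along the grid 0.5, 0.9, 0.99,
... until the pooled score set shows zero false positives, then one further
decade toward 1 as a safety step against overfitting of the scores
themselves (0.99999 becomes 0.999999). A negative example scoring exactly
1.0 means no valid threshold exists and is an explicit failure.

## The simulator and what passing tests mean

No raw recordings are available, so the package ships a forward model that
renders the study conditions: 1.67 um pitch, 650 nm, 26.7 fps, 120 frames,
1 s drive. Each object is a weak complex transmittance patch at its depth;
its scattered field is forward-propagated to the sensor (angular spectrum,
single-scattering superposition on a unit reference) and digitised with
Poisson shot noise and Gaussian read noise at 10-bit depth. Motion is
phenomenological, matched to what the magnetic drive produces:

* *Oscillating cells* follow a square-wave drive with first-order
  exponential relaxation toward each extreme (default relaxation 0.08 s,
  well under the 0.5 s half period). The roll is rendered as rotation of an
  asymmetric internal pattern of five bead-sized absorbers inside the cell
  disk, re-centred so appearance (not position) carries the oscillation,
  plus a small 1 px lateral rock.
* *Bead chains* swing between two orientations at the drive period with a
  faster relaxation (0.03 s) -- the major false-positive class.
* *Random walkers* take seeded Brownian steps (per-axis step variance
  $2D$); *static particles* and a static, slowly drifting background
  speckle field model debris.

Modulated objects are rendered on the full grid so their entire fringe
aperture reaches the sensor; small debris uses a cheap local window. The
default benchmark scene (`benchmarkScene()`) is a 256 px field of view with
6 cells at depths 850--1150 um (where the field of view subtends the full
pixel-limited aperture, making 10 um refinement physically meaningful), 20
walkers, 10 static particles, background speckle, slow horizontal drift, and
cell contrast set so the hologram signal-to-noise ratio is 7--9. The
desk-scale profile (`deskScene()`, `deskDepthGrid()`, `deskNetConfig()`,
`deskTrainConfig()`) shrinks the geometry (96 px FOV, 24 frames at 12 fps,
depths 600--1200 um, 16 px crops, three dense blocks) so that dataset
generation plus training run in minutes on one CPU; the problem sizes used
by the tests and the acceptance script are 200 videos per class, an 80/20
train/validation split, and 40 epochs at learning rate 1e-3.

What the simulator does *not* emulate bounds what green tests mean: the
magnetic force field is not simulated (motion is prescribed, not driven);
scattering is single-pass weak scattering, so dense debris, multiple
scattering, twin-image crosstalk from strong scatterers, aliasing from
super-Nyquist fringes, vibration, and illumination drift are absent; real
bead-cell conjugates have unknown amplitude/phase contrast (the defaults are
order-of-magnitude choices, exposed in `simObject()`). Passing the
end-to-end criteria demonstrates the pipeline's internal consistency under
the stated conditions, not performance on real blood.

## Numerical choices and degenerate inputs

* Frames per period must be even; the constructor rejects videos where the
  rounded value is not in $(0, N_F)$.
* Degenerate (all-equal) focus scores return the smallest depth with a
  warning; fine grids are clamped to the coarse grid's range.
* All-constant frames make phase correlation degenerate: zero shifts plus a
  warning.
* Negative contrast values are retained in the volume (the focus criterion
  sums raw values); projection and thresholding ignore them naturally.
* Every stochastic element (scene content, walker paths, noise, shuffling,
  dropout, augmentation) derives from explicit integer seeds; rendering and
  screening are bit-reproducible.
* Coordinates are 1-based (R convention) with x = column, y = row, origin
  at the top-left pixel, everywhere.

## Known limitations

Axial refinement to 10 um requires the local neighbourhood to subtend the
object's fringe aperture; for objects much deeper than ~1.5 mm a larger
neighbourhood (and field of view) than the defaults would be needed. The
per-candidate video is extracted from the full field of view, so the cost
grows with sensor area. The classifier's full-scale training protocol is
provided but is not exercised at full scale by the tests -- only the
desk-scale profile is, for tractability -- and the zero-false-positive
threshold transfers to new data only as well as the pooled score set
represents it.
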