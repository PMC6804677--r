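# holocyte

Rare cells in blood can be counted without any fluorescent label by tagging
them with antibody-coated magnetic beads, wiggling them with an alternating
magnetic field, and watching the resulting speckled in-line holograms with a
lens-free microscope. `holocyte` is an R implementation of the computational
side of such a cytometer: everything between the raw hologram video and a
cells-per-millilitre answer.

The pipeline, per field of view:

1. **Drift correction** — phase correlation against the middle frame,
   subpixel refinement, bilinear resampling (horizontal axis only by
   default, preserving the magnetically driven vertical motion).
2. **Volumetric reconstruction** — every frame `A_i` is refocused to a
   depth grid (800–5000 µm, 100 µm steps, 43 planes) by the angular
   spectrum method with a Gaussian spatial high-pass:
   `B_i(z_j) = HP[P(A_i, −z_j)]`.
3. **Periodic-motion contrast** — half-period and whole-period differences
   of the reconstructed amplitude images combine into
   `C = mean( ½|B_i − B_{i+N/2}| + ½|B_{i+N/2} − B_{i+N}| − |B_i − B_{i+N}| )`,
   which is positive only for content oscillating at the magnetic drive
   frequency (N frames per period; 26 at 26.7 fps and a 1 s drive). Static
   background cancels exactly; Brownian debris comes out negative.
4. **Detection** — maximum intensity projection over depth, adaptive
   thresholding (mean + 6 sd), 8-connected components, intensity-weighted
   centroids.
5. **Autofocusing** — per candidate, argmax over depth of the contrast sum
   in a 40 × 40 px (66.8 µm) window, then a 10 µm re-search around the
   coarse plane.
6. **Classification** — a densely connected pseudo-3D CNN (factored
   1×3×3 / 3×1×1 convolutions, dense channel concatenation with growth rate
   k = 8, 2×2×2 max pooling) scores each candidate's two-channel
   amplitude/phase video (2 × 120 × 64 × 64), trained with Adam and a
   zero-false-positive decision-threshold tuning rule (0.5, 0.9, 0.99, …
   plus one safety decade, e.g. 0.99999 → 0.999999).
7. **Counting** — positives over the whole-blood-equivalent volume
   (screened volume × 4 mL / 3.2 mL) give cells per mL of whole blood.

Because no raw recordings ship with the package, a simulator renders the
full study conditions (1.67 µm pitch, 650 nm, 26.7 fps, 120 frames, 1 s
drive) with ground truth: rolling bead-conjugated cells, swinging bead
chains, Brownian and static debris, background speckle, drift, shot and
read noise. The network and its training loop are implemented in the
package (R with compiled convolution kernels) and verified against
numerical gradients.

## A worked example

Simulate a field of view with six magnetically modulated cells among
thirty debris particles, screen it, and localise the cells in 3D:

```r
library(holocyte)

scene <- benchmarkScene(seed = 7)        # 256 x 256 px, 6 cells + 30 debris
sim   <- renderHologramVideo(scene)
video <- correctDrift(sim$video, estimateDrift(sim$video))
vol   <- motionContrastVolume(video, depthGrid())
cands <- detectCandidates(projectMaxIntensity(vol))
cands[, c("x", "y", "area", "peakScore")]   # one row per detected cell
for (i in seq_len(nrow(cands))) {
  cf <- autofocusCoarse(vol, cands[i, ])
  rf <- autofocusRefine(video, cands[i, ], cf$z, fineHalfspan = 250)
  cands$zRefined[i] <- rf$z
}
```

On this seed the pipeline detects all six cells with zero false detections;
matched against the simulator's ground truth the lateral centroid errors
are 0.3–1.7 px and the refined depths land within 2–17 µm of the true
positions (e.g. a cell at z = 1122 µm is refined to 1120 µm):

```
cand 1: laterr=1.71 px  zTrue=945   zRefined=940
cand 2: laterr=0.61 px  zTrue=1122  zRefined=1120
cand 3: laterr=0.28 px  zTrue=939   zRefined=930
cand 4: laterr=1.66 px  zTrue=997   zRefined=980
cand 5: laterr=1.56 px  zTrue=870   zRefined=860
cand 6: laterr=1.50 px  zTrue=853   zRefined=850
```

Training and applying the classifier (desk-scale profile, minutes on one
CPU):

```r
ds    <- generateLabelledDataset(200, c("bead_chain", "oscillating_cell"), seed = 11)
val   <- seq(1, length(ds$videos), by = 5)
y     <- as.integer(ds$labels) - 1L
model <- trainNetwork(buildNetwork(deskNetConfig(), seed = 11),
                      ds$videos[-val], y[-val],
                      config = deskTrainConfig(epochs = 40))
p     <- predictProbabilities(model, ds$videos[val])[, 2]
th    <- tuneDecisionThreshold(predictProbabilities(model, ds$videos)[, 2], y)
```

A thin command-line interface over the same functions lives at
`inst/cli/holocyte.R` (subcommands `simulate`, `screen`, `train`,
`tune-threshold`, `classify`, `report`).

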