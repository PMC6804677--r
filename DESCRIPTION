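Package: holocyte
Title: Rare-Cell Detection by Magnetically Modulated Lensless Speckle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a lensless holographic cytometer for rare
    cells that are magnetically labelled and oscillated by an alternating
    magnetic field. Implements angular-spectrum back-propagation with spatial
    high-pass filtering over a depth grid, phase-correlation drift correction,
    a periodic-motion contrast statistic (computational motion analysis) with
    maximum-intensity projection and threshold-based candidate detection,
    coarse and fine holographic autofocusing, extraction of per-candidate
    amplitude/phase videos, a densely connected pseudo-3D convolutional video
    classifier with its training protocol and zero-false-positive decision
    threshold tuning, a synthetic hologram-video generator with ground truth,
    and end-to-end screening with whole-blood concentration estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml, tiff, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
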