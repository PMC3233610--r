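Package: mbralign
Title: Likelihood-Based Matching of Peptide Features Across LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Match-between-runs for label-free LC-MS proteomics. Transfers
    peptide identities across runs by locating candidate elution peaks in
    extracted-ion chromatograms and scoring each candidate pair with a
    maximum-likelihood model that combines a Gaussian model of residual
    (warp-corrected) retention-time shifts with a Gamma model of peak-shape
    dissimilarity (one minus the alignment R-squared). Includes
    ground-truth-based polynomial retention-time warping, noise-adaptive peak
    interval detection, ROC diagnostics, multi-run identity propagation with
    coverage accounting, and a synthetic LC-MS experiment generator for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
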