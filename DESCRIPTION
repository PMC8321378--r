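Package: spagen
Title: Glaucoma Detection from Cup-to-Disc Ratio Profiles with a Spatial
    Generative Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage detection of glaucoma from optic cup and disc
    segmentation masks of fundus photographs.  The first stage extracts a
    24-direction cup-to-disc ratio (CDR) profile, the vertical CDR and the
    cup-to-disc area ratio (CDAR) from a label mask by radial ray casting
    from the disc centroid.  The second stage fits SpaGen, a hierarchical
    Gaussian generative model of the profile with a two-harmonic Fourier
    mean per diagnostic group, a per-eye random effect and group-specific
    noise variances, and classifies eyes by the Bayes posterior probability
    of glaucoma or the equivalent Rim Deformation Score.  Also included are
    a compact U-shaped fully convolutional segmentation network with a
    mobile inverted-bottleneck encoder trained by built-in backpropagation,
    segmentation and diagnostic evaluation metrics (Dice, Jaccard, AUROC,
    ROC-optimal thresholds, Bland-Altman agreement), and generators for
    synthetic profiles, elliptical masks and pseudo-fundus images so that
    every stage can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
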