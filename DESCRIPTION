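Package: octchoroid
Title: Automated Choroid Segmentation and Subfoveal Choroidal Thickness
    Measurement for OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for measuring subfoveal choroidal thickness
    (SfChT) on optical coherence tomography (OCT) B-scans. Provides a synthetic
    layered-phantom generator with pixel-perfect ground truth, encoder-decoder
    segmentation networks (U-Net and residual variants) with a strip-pooling
    bottleneck and late probability fusion, dice-loss training with online
    augmentation, Dice score and average symmetric surface distance evaluation,
    Otsu-based fovea localization, per-column thickness extraction, and a
    longitudinal two-arm cohort simulator with change-from-baseline,
    covariate-adjusted group contrasts, Pearson association and hierarchical
    multiple regression analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
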