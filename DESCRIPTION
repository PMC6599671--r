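Package: opticdisc
Title: Optic Disc Localisation in Colour Fundus Images by Multispectral
    Analysis and Information Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic localisation and circular delineation of the optic
    disc in colour retinal fundus photographs.  A coarse phase combines the
    maximum multilevel-Otsu intensity class of the red, green and blue
    channels to find the region of interest; a fine phase suppresses blood
    vessels by grayscale closing, picks the colour channel with the highest
    Shannon entropy inside the region, and fits the disc with a circular
    Hough transform.  Includes the standard centre-error and mask-overlap
    evaluation metrics (normalised centre distance, TPR/FPR/accuracy,
    percentage overlap, Dice index, mid-p McNemar comparison), a seeded
    synthetic fundus-phantom generator with exact ground truth, and batch
    helpers for directory-level detection and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
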