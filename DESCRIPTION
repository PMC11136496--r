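Package: ehtkit
Title: Quantitative Image Analysis of Endothelial-to-Hematopoietic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the endothelial-to-hematopoietic
    transition (EHT) in the zebrafish dorsal aorta: unwrapping of the tubular
    aortic wall into 2D cartographies with back-mapping and perimeter
    measurement, cell morphometrics (moment ellipse, elongation, orientation,
    neighbor counts) and rule-based cell-type classification, FRAP
    recovery-curve normalization and single-exponential fitting (mobile
    fraction, half-time, early slope), single-molecule FISH spot spatial
    statistics (spots per cell, 50%/75% attraction distances), a hematopoietic
    cell counter for dual-channel stacks (rolling-median transient removal,
    top-hat segmentation, watershed splitting), and qRT-PCR delta-delta-Ct
    with Dixon's Q outlier gating. Every stage is exercisable on synthetic
    phantoms with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    mgcv,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
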