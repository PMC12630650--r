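Package: biofilmph
Title: Microscale pH Ratiometry and Lectin Biovolume Analysis of Dental
    Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of in situ-grown dental biofilms from
    split-mouth (within-patient paired) study designs. Converts two-channel
    confocal images of the ratiometric dye C-SNARF-4 into extracellular pH
    maps through a fitted four-parameter calibration curve, quantifies
    microbial and lectin-stained matrix biovolumes from multi-slice
    confocal z-stacks by intensity-threshold segmentation (total,
    layer-stratified, and intercellular), and provides the paired
    downstream statistics: centered log-ratio based differential abundance
    with Wilcoxon signed-rank tests and Benjamini-Hochberg correction,
    principal component analysis of community composition, hierarchical
    (mixed-effects) estimation of treatment effects on pH and biovolume,
    and power/sample-size computations. Includes seeded synthetic-data
    generators that emulate the full study layout (calibration buffer
    image sets, single-slice ratio fields of view, six-slice lectin
    z-stacks, and paired amplicon count tables) with ground truth attached,
    so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    emmeans,
    jsonlite,
    lmerTest,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
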