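Package: telostorm
Title: Telomere Shape and Protection Analysis from Super-Resolution and Blot Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative pipeline for studies of telomeric chromatin
    structure and protection. Simulates 3D STORM molecule lists, nuclear
    foci images, gel lane profiles and ChIP dot blots with known ground
    truth; drift-corrects localization tables by image cross-correlation;
    identifies telomere clusters by density-based clustering and scores
    their shape with the radius of gyration, principal-axis anisotropy,
    and the fraction of irregular telomeres above a reference-mean cutoff;
    scores telomere dysfunction-induced foci (TIF) and two-channel
    colocalization percentages under an identical-threshold policy;
    computes intensity-weighted mean telomere restriction fragment length
    with ladder calibration and dot-blot input/H3 normalization; and
    compares groups with t tests, one-way ANOVA with Dunnett contrasts,
    and Tukey multiple comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    multcomp,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
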