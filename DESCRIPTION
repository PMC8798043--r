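Package: punctakit
Title: Scale-Space Spot Detection and Quantification for Membrane
    Fluorescence and AFM Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for sub-micrometric protein assemblies
    (puncta, molecular clusters) on membranes, built around a
    Laplacian-of-Gaussian scale-space spot detector with cross-scale
    linking and area-overlap merging. Includes intensity quantification
    and fold-change analysis on detected structures, kymograph
    construction and recruitment-kinetics fitting, AFM height-map
    leveling with cluster segmentation and particle tracking,
    docking-event interval statistics, and the statistical tests used
    for such comparisons (Welch's t-test, one-way ANOVA with Dunnett's
    multiple comparisons). A synthetic-data module generates calibrated
    fluorescence stacks, AFM maps and movies with known ground truth so
    every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    yaml,
    minpack.lm,
    mvtnorm,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
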