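Package: scqpcr
Title: Single-Cell qPCR Subpopulation Analysis and Tissue-Repair Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microfluidic single-cell qPCR experiments
    (e.g. Fluidigm 96.96 dynamic arrays): reads cycle-threshold (Ct) tables
    with failed-amplification masks, normalizes to bounded log2 expression
    relative to pooled per-gene medians with non-expresser flooring, discovers
    cell subpopulations by k-means partitioning (within-cluster sum of squares
    objective, silhouette-based choice of k) with complete-linkage hierarchical
    sub-grouping for clustergram visualization, tests per-gene differential
    expression between clusters or groups with two-sample Kolmogorov-Smirnov
    tests under Bonferroni correction, and matches clusters across
    independently clustered groups to flag absent or depleted subpopulations.
    Also provides immunofluorescence stain-area-per-cell quantification
    (automated DAPI thresholding, fixed stain thresholds, nucleus size
    filtering), caliper tumor volume/density and wound-closure morphometry,
    and a synthetic-data generator that emulates the 96-gene by 384-cell
    study design with planted subpopulations, dropout, and group-specific
    cluster presence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
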