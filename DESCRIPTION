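Package: chromquant
Title: Quantitative Analysis of Heterochromatin Remodeling in the 2C-Like
    Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chromatin organization in the two-cell-like
    (2C-like) to pluripotent transition of embryonic stem cells:
    Voronoi-tessellation density analysis of single-molecule localization
    (STORM) data as a measure of DNA compaction, GFP-reporter intensity
    scoring and 2C-positive classification of nuclei, chromocenter (H3K9me3)
    foci segmentation and per-focus quantification, Manders colocalization
    coefficients, and downstream chromatin-bound proteome (chromatome)
    enrichment analysis of peptide-spectrum-match counts with fold-change
    selection and Venn set decomposition. Includes seeded synthetic-data
    generators with ground truth for every analysis (clustered localization
    point patterns, multichannel nucleus images with controllable focus
    overlap, negative-binomial PSM tables with spike-in proteins) so each
    estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    multcomp,
    purrr,
    rlang,
    spatstat.geom,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
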