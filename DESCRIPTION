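Package: metaboprog
Title: Serum Metabolomics Analysis of Disease Motor-Progression Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for untargeted LC-MS serum
    metabolomics aimed at distinguishing slow from rapid motor-progression
    phenotypes. Provides feature-table input/output, technical-replicate
    quality control (detection and coefficient-of-variation filters),
    UPDRS-based progression phenotyping with top-quartile classification,
    metabolome-wide two-sample testing with Benjamini-Hochberg false
    discovery rate control and Manhattan-plot data, orthogonal signal
    correction followed by NIPALS partial least squares discriminant
    analysis with loading-correlation (PCLS) feature selection, weighted
    correlation network analysis with topological overlap, module
    eigengenes and eigengene-network module preservation between cohorts,
    single-point response-factor absolute quantification with one-way
    ANOVA and Tukey post tests, and a synthetic cohort generator with
    planted effects and correlation modules for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    yaml
Config/testthat/edition: 3
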