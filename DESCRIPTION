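Package: lineageprime
Title: Lineage-Specific Expression Signatures and Priming Analysis for
    Sorted Gonadal Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for FACS-sorted cell population expression
    profiling of the developing mouse gonad: pairwise-comparison list
    algebra over a log2 expression matrix (difference and identity calls
    composed by intersection), sex-specific and sex-independent
    lineage-enriched/depleted signatures, Leydig-cell contamination
    deconvolution, lineage-priming classification by three methods with
    similar/intermediate expression tagging, exact binomial tests of
    biased-differentiation models and a two-sided 2x2 exact independence
    test, permutation-based list-level false discovery rates, global
    structure diagnostics (hierarchical clustering of arrays, per-gene
    ANOVA sources of variation), symbol-based cross-dataset integration,
    and a synthetic-data generator with planted ground truth that
    emulates the 4-lineage x 2-sex x 3-stage x 3-replicate study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
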