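Package: gtscreen
Title: Haploid Gene-Trap Screen Enrichment Analysis and Dose-Response Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of reporter-based haploid gene-trap insertional mutagenesis
    screens and of four-parameter logistic (4PL) dose-response titrations.
    Classifies mapped gene-trap insertion sites (exonic/intronic, sense/antisense,
    inactivating) against strand-aware gene models, computes per-gene enrichment
    of inactivating insertions in a sorted cell population over a control
    population with a one-sided Fisher exact test and Benjamini-Hochberg FDR
    correction, scores the intronic gene-trap insertion orientation bias (IGTIOB)
    per gene, and compares screens by clustering significant genes on their
    IGTIOB scores. Fits variable-slope four-parameter logistic curves to reporter
    titrations to estimate EC50 values with standard errors, fold-changes in
    potency, efficacy ratios, and Welch t-test comparisons of EC50s. A synthetic
    data module simulates annotations, screens with planted hit genes, and noisy
    titrations for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    minpack.lm,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
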