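Package: hgsocTyper
Title: Two-Type Classification of High-Grade Serous Ovarian Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies high-grade serous ovarian carcinoma (HGSOC)
    transcriptomes into HRR-activated and mesenchymal subtypes. Provides a
    38-gene geometric-mean EMT index with median-split stratification,
    PCA/K-means and hierarchical two-cluster subtyping with PC1-correlated
    gene selection, hypergeometric gene-set overrepresentation against GMT
    libraries with Benjamini-Hochberg FDR control, homologous-recombination-
    deficiency genomic scar scores (LOH, NtAI, LST) from allele-specific
    copy-number segments, contingency-table and rank statistics for cohort
    comparison, Kaplan-Meier/log-rank survival analysis, and a seeded
    synthetic two-subtype cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
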