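Package: rccmatch
Title: Matching Renal Cancer Cell Lines to Tumour Subtypes by Genomic Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading how faithfully renal cell carcinoma (RCC) cell
    lines represent tumour subtypes using somatic copy-number, mutation and
    expression data. Implements harmonization of heterogeneous copy-number
    inputs (log2 ratio and allele-specific integral calls), fraction genome
    altered and chromosome-arm loss statistics with a minor-allele LOH
    estimator that detects losses masked by major-allele amplification,
    co-clustering of tumours and cell lines on gene-level copy number with
    Spearman distance and average linkage, a three-tier cross-database
    concordance scheme for mutations and copy-number calls, aggressiveness
    comparisons of tumours that do or do not co-cluster with cell lines, an
    empirical-Bayes batch correction and nearest-shrunken-centroid ccA/ccB
    expression classifier with a correlation-margin calling rule, and a
    seeded synthetic-cohort generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    sva,
    mclust,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
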