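Package: linckit
Title: Discovery and Characterization of Cardiac Long Intergenic Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a cardiac lincRNA discovery and
    characterization workflow for a three-tissue (embryonic heart, adult
    heart, adult muscle) RNA-seq design. Provides a six-filter lincRNA
    identification cascade over an assembled transcriptome (intergenic
    class codes, structural and expression filters, CPAT-style coding
    potential, Pfam/CPC/PhyloCSF score gates), tissue-enrichment and fetal
    gene-program classification, phastCons-style conservation scoring, a
    ternarized expression-based gene-set association matrix with permutation
    FDR, hierarchical and K-means/silhouette clustering, and UCSC-chain
    ortholog projection. Ships a synthetic-data generator that plants
    machine-readable ground truth so every stage is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    glmnet,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
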