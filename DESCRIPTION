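Package: polytrans
Title: Polysome-Profiling Translatome Analysis of Fraction-Resolved RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing fraction-resolved polysome-profiling RNA-seq
    experiments: CPM/TPM normalisation with expression and replicate-variability
    filters, per-fraction differential translation using gene-wise linear models
    with empirical-Bayes variance moderation, translation-ratio and
    translation-efficiency metrics, clustering of translation behaviours with
    hierarchical, k-means and Gaussian-mixture models selected by BIC and
    silhouette, mRNA sequence and structure features (5'TOP scoring, uORF
    detection, codon adaptation index, folding energy per base), hypergeometric
    over-representation analysis, and a negative-binomial simulator with planted
    translational regulation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    cluster
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
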