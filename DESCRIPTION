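Package: centrosat
Title: Alpha-Satellite Higher-Order Repeat Annotation and Population Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates alpha-satellite higher-order repeats (HORs) in human
    centromeres from long reads and assemblies. Provides a k-mer/PCA/SVM read
    classifier for extracting chromosome-specific alpha-satellite reads, a
    template-scan array builder that concatenates satellite regions into
    per-chromosome arrays, a StringDecomposer-style dynamic-programming block
    decomposer with monomer labeling, hierarchical tandem repeat mining with
    shift/reverse pattern canonicalization and locally nested subunit
    detection, coverage-normalized cross-sample HOR quantification with
    variable-HOR calling and centromere genotype clustering, cross-landscape
    HOR unit clustering and ancestral HOR reconstruction, and a synthetic
    centromere simulator with planted ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    e1071,
    igraph,
    ape,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Annotation, Sequencing, RepeatAnalysis, Clustering
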