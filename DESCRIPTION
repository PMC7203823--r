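Package: veqtl
Title: Mapping Environmental-Variance QTL for Litter Size from SNP and
    Pooled Whole-Genome Sequence Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to map loci controlling the environmental (residual)
    variance of litter size in divergently selected rabbit lines.
    Implements per-doe environmental-variance phenotypes from repeated
    litter records, genotype quality control with genomic relationship
    matrices and principal components, single-marker mixed-model
    association with leave-one-chromosome-out relationship matrices,
    a Bayes B multiple-marker Gibbs sampler with Bayes factors and
    1-Mb window variance partitioning, permutation and within-population
    validation of candidate SNPs, linkage-disequilibrium-based vQTL
    region definition, and a pooled-line whole-genome variant screen
    (hard filtering, consequence selection, segregation classification,
    candidate gene intersection). A synthetic-data module emulates the
    full data structure so the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
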