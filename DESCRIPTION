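Package: m6akit
Title: Base-Resolution m6A Quantification, Site Calling, Orthogonal
    Validation and QTL Mapping
Version: 0.1.0
Authors@R:
    person("m6akit", "Developers", email = "maintainer@m6akit.org",
           role = c("aut", "cre"))
Description: A toolkit for integrative epitranscriptomics: builds strand-aware
    single-base reference sets of exonic DRACH adenosines from a genome and
    annotation, quantifies N6-methyladenosine (m6A) methylation against those
    sites from read alignments under antibody (IP/input overlap) and
    base-conversion (pileup) contracts, performs uniform site calling with a
    one-sided binomial test against the sample-wide background rate
    (Benjamini-Hochberg corrected) and a two-component beta-binomial mixture
    classifier fitted by EM, calibrates false positives with in-vitro
    transcribed (IVT) negative controls, validates sites and differential
    methylation across technically orthogonal assays with a Gaussian copula
    mixture irreproducible discovery rate (IDR) model, and maps cis m6A
    quantitative trait loci from normalized log-odds methylation levels with
    permutation-based empirical p-values and a beta-tail approximation.
    Includes a synthetic-data module that generates toy genomes, count
    matrices with planted truth, SAM reads, IVT nulls, correlated technique
    pairs and genotype cohorts for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    splines,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
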