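Package: crisprmat
Title: Pooled CRISPR Screen Design, Deconvolution and Epigenome
    Integration for Cardiomyocyte Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for an in vivo pooled CRISPR knockout screen for
    regulators of cardiomyocyte maturation, and for linking H2B
    monoubiquitination (H2Bub1) dynamics to maturational gene expression.
    Implements sgRNA library design by a five-tier rule cascade
    (constitutive-exon and CDS-position filters, off-target mismatch
    profiling, microhomology out-of-frame scoring, SapI oligo
    construction), screen read trimming and guide counting with
    three-criterion sample QC, per-guide negative-binomial Wald tests
    with median-of-ratios normalization, alpha-robust-rank-aggregation
    gene scoring, histone-mark ChIP signal quantification (gene-body,
    TSS-window and RPKM schemes), preranked gene-set enrichment, and
    quadrant contingency integration of maturational RNA and H2Bub1
    changes. Ships a deterministic synthetic-data generator (genome,
    annotation, screen reads/counts, ChIP and RNA count tables with
    planted ground truth) that the test-suite uses for parameter-recovery
    and calibration checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    IRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
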