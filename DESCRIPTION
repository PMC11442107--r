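Package: panelgwas
Title: Population Structure, LD Decay and Mixed-Model GWAS for Inbred
    Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-wide association analysis of
    fully inbred crop diversity panels genotyped at biallelic SNPs. Provides
    VCF import with the marker-level post-filters used for inbred panels
    (heterozygote masking, minor-allele-frequency and missingness filters,
    window-based pruning), principal component analysis and neighbor-joining
    phylogeography with bootstrap support and geographic enrichment,
    linkage-disequilibrium decay curve fitting with an extended Hill-Weir
    hyperbolic model and the half-decay distance d_LD50, genomic-relationship
    mixed-model association scans for binary (logistic, via penalized
    quasi-likelihood) and quantitative responses with conditional fixed
    effects and Benjamini-Hochberg FDR thresholds, and a d_LD50-window QTL
    region caller with peak-genotype correlation and local LD reporting. A
    founder-mosaic genotype simulator generates inbred panels with realistic
    LD structure, geographic clines and a binary trait under major-gene plus
    complementary-modifier control, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
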