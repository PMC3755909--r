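Package: kaikobuild
Title: Evidence-Based Gene Building and Tissue-Specific Cluster Analysis
    from Full-Length cDNA Evidence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building an evidence-based gene set for a
    lepidopteran-style genome from full-length cDNA (FL-cDNA), EST and
    public mRNA evidence, and for the downstream statistics such a build
    supports. The package clusters 5' ESTs into contigs by a sequence
    identity rule, maps transcripts to the genome with a splice-aware
    dynamic-programming aligner behind identity/coverage prefilters, flags
    chimeric clones by a genomic co-localization criterion, partitions the
    evidence into mapped gene loci, EST-only loci and unmappable sequence
    clusters, profiles per-locus tissue expression from EST library
    provenance, detects tissue-specific chromosomal gene clusters with a
    Fisher exact adjacency test, and summarizes ortholog-group tables.
    A deterministic synthetic-data generator emulates the genomic and
    library structure these analyses assume (transposon-inflated introns,
    a Z-like chromosome enriched for testis-specific genes, planted
    ovary-specific clusters, 5'-truncated error-bearing ESTs, poly-A
    tails and chimeric clones) together with a ground-truth table for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Alignment, GenePrediction, Transcriptomics, Clustering,
    Sequencing, Software
RoxygenNote: 7.3.3
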