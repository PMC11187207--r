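Package: scEmbryoRT
Title: Single-Cell Replication Timing and Copy-Number Fragility Analysis
    for Early Embryos
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing DNA replication timing and chromosome
    fragility in shallow whole-genome-sequenced single blastomeres from
    cleavage-stage embryos. Implements per-cell quality control against a
    G1 reference (GC and amplification-trend correction, MAD scores, phase
    calling), binarization of S-phase cells into replicated/unreplicated
    bins and aggregation into replication-percentage profiles with
    early/late classification, per-cell copy-number segmentation with
    break-site annotation at copy-number transitions greater than one,
    enrichment of sites against length-matched random genomic regions
    (gene/origin density, lamina-association observed/expected ratios,
    A/B compartment sign, Mann-Whitney and one-way ANOVA tests), and DNA
    fiber arithmetic (fork speed, inter-origin distances). Ships a
    synthetic-data generator with a known replication-timing program and
    injectable copy-number events so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: SingleCell, CopyNumberVariation, Epigenetics, Coverage,
    Sequencing
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
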