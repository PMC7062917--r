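Package: methylscape
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis with
    Sliding-Window DMR Detection and Drug-Synergy Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of whole-genome bisulfite sequencing
    (WGBS) data in species that methylate cytosines in CG, CHG and CHH
    contexts. Provides context calling from a reference genome,
    methylation-level estimation with correction for incomplete bisulfite
    conversion estimated from an unmethylated lambda spike-in, sliding
    window and fixed-bin genome-wide methylation summaries, 20-bin
    metaprofiles over gene functional elements, differentially methylated
    region (DMR) detection by a sliding-window Fisher's exact test with a
    coverage/effect-size/FDR filter cascade, DMR-to-gene annotation with
    hyper/hypo classification and per-gene methylation ratios,
    hypergeometric term over-representation tests, and median-effect
    dose-response fitting with Chou-Talalay combination-index synergy
    scoring. A seeded synthetic-data generator produces complete input
    bundles (toy genome with lambda control chromosome, gene models,
    per-cytosine count reports with planted DMRs, dose-response tables)
    so every step of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, Sequencing, Software
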