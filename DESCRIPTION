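Package: dsb3d
Title: Multiscale Hi-C and Translocation Analytics for DNA Double-Strand Break Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how DNA double-strand breaks (DSBs)
    reorganize the 3D genome and drive chromosomal translocations. Provides
    sparse binned contact-matrix input/output in a cooler-dump-compatible text
    dialect, iterative-correction (ICE) balancing, distance-decay expected
    models and observed/expected transforms, contact-probability scaling P(s)
    with its log-log derivative, diamond-window insulation, A/B compartment
    eigenvectors phased by gene density, compartment-flip detection, saddle
    plots and saddle strength, aggregate pileups at damaged-site pairs and
    oriented CTCF anchors with cluster-enrichment and convergent-loop scores,
    a constrained-resampling control null, and high-throughput genome-wide
    translocation sequencing (HTGTS) junction analytics: bait-only-normalized
    frequency tables, prey-distance classes, microhomology/blunt/insertion
    junction classification, insertion mapping, region annotation, and
    differential comparisons between treatment conditions. A fully
    parameterized synthetic-data generator plants compartments, flips, loops,
    focal DSB clustering and junction-class mixtures so every estimator can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
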