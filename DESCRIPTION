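Package: triplesites
Title: Combinatorial Occupancy and Motif-Oriented Architecture of CTCF/Cohesin/TOP2B Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the combinatorial occupancy and spatial
    organisation of architectural proteins (CTCF, cohesin, topoisomerase II
    beta) around oriented CTCF motifs. Implements interval merging and
    occupancy classification of multi-factor ChIP-seq peak sets, position
    weight matrix scanning with exact tail p-values and permuted-matrix
    backgrounds, signed motif-oriented summit distance and ordering
    statistics, base-pair resolution strand-resolved ChIP-exo 5'-end
    protection profiling with footprint calling, allele-specific binding
    classification from F1-cross read counts, DNA supercoiling probe
    profiles around oriented features, and relative positioning of sites
    within topological domains. A seeded synthetic-data generator plants
    ground truth (motif instances, occupancy classes, summit offsets,
    footprint boundaries, allelic biases, supercoiling dips, domain-border
    placement) so that every analysis stage can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
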