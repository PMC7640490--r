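Package: inschar
Title: Characterization, Simulation and Benchmarking of Insertion Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize sequence-resolved insertion variants (>= 50 bp)
    from VCF callsets. Classifies insertions into five sub-types (tandem repeat,
    mobile element, tandem duplication, dispersed duplication, novel sequence)
    with a coverage-threshold decision tree, measures junctional homology at
    breakpoint junctions with a two-tier (strict scan plus alignment) detector,
    annotates the genomic context of insertion sites against repeat and gene
    tracks, simulates scenario-structured insertion datasets as mutated
    reference plus truth VCF pairs, and scores external SV-caller callsets with
    insertion-site and sequence-resolved recall definitions. Includes a
    synthetic-data generator producing annotated random genomes, mobile-element
    consensus libraries and labeled callsets for download-free validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
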