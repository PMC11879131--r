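Package: circpie
Title: Design and Sequencing Analysis of Permuted Intron-Exon Circular RNA
    Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models permuted intron-exon (PIE) precursors built from group I
    introns and analyses the deep-sequencing readouts used to characterize
    them: SHAPE-MaP mutational-profiling reactivities with per-domain
    structural divergence between native and permuted intron forms, SPLASH
    proximity-ligation chimeric-read interaction maps with differential
    testing, randomized-exon (N60) junction-library motif analysis,
    splice-junction error profiling, and replicate-intersected variant
    frequency enrichment. Includes seeded simulators that generate every
    read-level input with planted ground truth, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
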