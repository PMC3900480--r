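Package: mirflow
Title: Small RNA-Seq MicroRNA Profiling for Staged Embryonic Muscle Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for
    microRNA discovery and expression profiling across developmental-stage
    libraries. Implements adapter-aware read filtering with a categorized
    discard taxonomy, collapsing to unique reads, hierarchical small-RNA
    class annotation with an ungapped mismatch-tolerant mapper, known-miRNA
    identification with family collapsing and hairpin verification,
    positional nucleotide-bias profiling, novel-miRNA calling from folded
    genomic flanks under stem-loop structural criteria, count-based pairwise
    differential expression with the Audic-Claverie statistic, seed-rule
    miRNA target scanning with G:U wobble, and delta-delta-Ct qPCR
    quantification. Includes a seeded synthetic-data generator that plants
    miRNA loci, contaminant classes and fold changes so every stage can be
    validated against ground truth. A bundled nearest-neighbor RNA folding
    engine provides minimum-free-energy hairpin structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
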