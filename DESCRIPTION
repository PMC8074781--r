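Package: mitoforge
Title: Reference-Assisted Mitogenome Assembly, NUMT Discovery, and
    Mitogenomic Diversity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling circular mitochondrial genomes that carry
    a duplicated control region, built around a supervised reference-assisted
    de Bruijn k-mer walkthrough with explicit, evidence-based arbitration of
    assembly bifurcations (PCR product sizes, paired-end inserts, spanning
    long reads). Companion modules cover canonical k-mer counting and
    read recruitment, solid/weak long-read trimming, detection of nuclear
    copies of mitochondrial DNA (NUMTs) by seeded local alignment with
    identity-threshold calibration, hybridization-capture bait tiling and
    consensus calling, per-window variant-density tracks, nucleotide
    diversity, pairwise identity matrices, and Fitch parsimony statistics
    (tree length, consistency, retention, and rescaled indices) on fixed
    topologies. A seeded synthetic-data generator emulates the target data:
    a parrot-style mitogenome with two nearly identical control-region
    copies, NUMT-bearing nuclear backgrounds, paired-end and error-prone
    long reads, and amplicon evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    withr,
    jsonlite,
    ggplot2,
    generics,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
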