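Package: cggcat
Title: Genome-Wide CGG Short Tandem Repeat Cataloguing and Population
    Polymorphism Analysis
Version: 0.1.0
Authors@R:
    person("CGG", "Catalogue Maintainers", email = "cggcat@example.org",
           role = c("aut", "cre"))
Description: Builds a genome-wide catalogue of CGG-class short tandem
    repeats from a reference FASTA (exact-frame seeding, wraparound
    dynamic-programming scoring with Tandem Repeats Finder style
    parameters, local-alignment boundary refinement), ingests diploid
    repeat-unit genotypes from ExpansionHunter/GangSTR style VCFs,
    computes locus- and sample-level polymorphism statistics against the
    population median repeat length, classifies concordance between two
    genotypers' call sets, annotates loci with gene-region labels using a
    1-kb upstream/downstream rule, tests gene-panel enrichment with a 2x2
    chi-squared statistic, and ships a seeded synthetic-data generator
    (planted repeats, cohort allele simulation with length-dependent
    instability, read-length censoring at about 50 units) so the full
    pipeline is testable without reference or cohort downloads.
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
    VariantAnnotation,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
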