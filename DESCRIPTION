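Package: pulascreen
Title: Gene-Targeted Screening of Shotgun Metagenomes for Disruptive
    Amylopullulanase Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens shotgun metagenome reads against a single reference
    gene locus for function-disrupting variation, modelled on the
    Lactobacillus crispatus amylopullulanase (pulA) gene. Provides a
    seed-and-extend local read aligner for a single-locus target, pooled
    continuous allele-frequency variant calling with codon-aware impact
    annotation, soft-clip based structural-variant and transposase
    insertion detection against a greedily clustered mobile-element
    database, per-sample intact/disrupted classification with cohort
    summaries, locus-model utilities (IUPAC motif scanning, palindrome
    testing, amplicon arithmetic), a synthetic cohort generator with
    machine-readable ground truth, and not-detected-aware log2 ratio
    analysis of label-free proteomics quantity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
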