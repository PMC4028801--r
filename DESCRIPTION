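Package: intronminer
Title: Discovery and Annotation of Group II Intron Retroelements in Genomic Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A staged pipeline for discovering group II intron retroelements in
    GenBank-format genomic sequence. Candidate intron-encoded proteins (IEPs) are
    found by translated local-alignment search with Karlin-Altschul E-values,
    non-group-II reverse transcriptases are screened out by top-match voting
    against a categorized RT reference set, candidates are assigned to intron
    classes, ORF domain architecture and intactness are verified against
    reference IEPs, ribozyme 5' and 3' boundaries are predicted with
    class-specific profile models scored by two algorithms, and the surviving
    full-length introns are reduced to a non-redundant prototype set by
    maximum-likelihood protein distances and single-linkage grouping at 95
    percent identity. Includes a deterministic synthetic-fixture generator that
    plants full introns, truncations, frameshifts and decoy RTs with a ground
    truth table, so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: mafft (for progressive alignment in the redundancy stage)
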