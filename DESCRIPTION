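Package: retromine
Title: Mining and Classification of Archaeal-Type RNase H Retrotransposons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering retrotransposons that carry
    an archaeal-type ribonuclease H (aRNH) domain in genome assemblies.
    Profile models of protein domain families are built from seed alignments
    and searched against six-frame translations with a local Viterbi decoder;
    aRNH anchors are expanded into candidate loci, classified by co-localized
    reverse-transcriptase evidence into LTR retrotransposons, non-LTR
    retrotransposons, or RT-free individual RNH genes, annotated structurally
    (ORFs, LTR pairs, CCHC zinc knuckle, chromodomain, catalytic residues),
    assigned to element groups (Chronos, Archon, L1, Utopia), and summarised
    as per-genome count tables. Distance-based phylogenetics (neighbor
    joining with column-resampling bootstrap) confirms group membership and
    splits RT-free aRNH copies into clades. A synthetic-genome generator
    plants divergence-controlled element copies with ground truth so that
    every stage can be scored for precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
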