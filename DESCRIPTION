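Package: baculokit
Title: Annotation and Comparative Genomics of Circular Baculovirus Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating circular double-stranded DNA virus genomes
    (granuloviruses and other baculoviruses) and comparing them across
    species. Implements ATG-initiated ORF calling on both strands of a
    circular genome with a minimal-overlap selection rule, IUPAC motif
    scanning for early (TATA + CAKT) and late (DTAAG) baculovirus promoter
    elements, discovery of imperfect palindromes and homologous regions (hrs)
    with a nearest-neighbor hairpin stability score and non-hr origin
    flagging, reciprocal-best-hit ortholog tables and gene-content
    classification, gene-parity synteny with inversion detection, and
    concatenated core-gene distance phylogenies (gamma-corrected distances,
    UPGMA, site bootstrap). A synthetic-genome generator with exact truth
    tables makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
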