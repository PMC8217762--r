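Package: famevo
Title: Gene-Family Evolution Analysis: Domain-Hit Families, Tandem
    Duplication, Neighbor-Joining Phylogenetics, Phylostratigraphy and
    MirrorTree Co-Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for comparative analysis of protein gene families
    (e.g. the Wnt and DIX families of the Wnt signalling pathway): family
    membership from HMMER domain hits with E-value/score filtering,
    molecular weight and isoelectric point computation (Bjellqvist pK set,
    bisection), domain-architecture strings, chromosomal distribution and
    tandem-duplication detection by gene-order adjacency, neighbor-joining
    trees with column-resampling bootstrap supports, ortholog-pattern
    phylostratigraphy with background comparison, MirrorTree-style
    co-evolution scoring between two families, and fold-change/Welch
    differential-expression classification. Includes seeded synthetic-data
    generators (trees, sequence evolution, genomes with planted tandem
    groups, ortholog tables, expression matrices) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    multcomp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
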