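Package: mitodrl
Title: Mitochondrial Gene-Order Evolution Under the Duplication-Random-Loss Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing mitochondrial gene-order rearrangement by
    tandem duplication followed by random gene loss (DRL). Provides readers and
    writers for annotated circular mitogenomes (FASTA plus a GFF3-subset feature
    table), circular gene-order extraction and comparison, inference of
    single-event DRL scenarios that explain a derived gene order, quantification
    of duplicate-gene decay (global affine-gap alignment, substitution and indel
    accounting, open-reading-frame scanning under the vertebrate mitochondrial
    code, paralog status calls), Jukes-Cantor-corrected average pairwise
    divergence (D_XY) between gene-order haplotype groups, Fitch parsimony
    mapping of gene-order characters onto a species tree, and a seeded simulator
    of annotated mitogenomes undergoing duplication, sequence decay and
    segmental deletion with full ground-truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
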