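Package: comparakit
Title: Desk-Scale Comparative Genomics Post-Processing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing stages of a comparative genomics production
    pipeline at desk scale: chaining and netting of pairwise whole-genome
    alignment blocks, two-pass large-scale synteny block construction,
    gene-tree/species-tree reconciliation with duplication-consistency
    scoring, dubious-duplication relabelling, gene-split detection and
    merging, orthologue/paralogue extraction with phylogenetic dating,
    projection of low-coverage genomes into reference-anchored multiple
    alignments, multi-resolution conservation-score stores, constrained
    element coverage accounting, cross-release stable identifier
    assignment, and consensus protein-family naming. Includes deterministic
    synthetic-data generators with ground-truth labels, readers and writers
    for AXT, MAF, Newick/NHX, BED, fixedStep wiggle, EMF and OrthoXML, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
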