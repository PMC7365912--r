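Package: nlrtrace
Title: Evolution of NBS-Encoding Disease-Resistance Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomic analysis of plant NBS-encoding (NLR)
    disease-resistance gene families. Builds domain-architecture strings and
    assigns TNL/CNL/RNL subclasses from domain-hit tables, detects tandem
    gene clusters on chromosomes by an intergenic-distance rule, profiles the
    six conserved NBS-domain motifs and their subclass-diagnostic residues,
    reconciles gene trees with a species tree by LCA mapping with
    duplication/loss parsimony, enumerates ancestral gene lineages and
    propagates copy-number ledgers to derive expansion/contraction patterns,
    detects collinear blocks by anchor chaining and classifies duplicates as
    tandem, dispersed or WGD/segmental. Includes birth-death and layout
    simulators that generate every input format with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
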