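Package: genelossr
Title: Detection, Filtering, Dating and Phenotype Association of Gene-Loss
    Events from Reference-Anchored Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens reference-anchored pairwise genome alignments of many
    species for gene-inactivating mutations (frameshifting indels,
    premature stop codons, splice-site disruptions, large frame-preserving
    indels, and exon or gene deletions), applies a cascade of filters that
    remove assembly, alignment, and gene-structure artifacts, summarises
    each gene per species by the maximum percentage of intact reading
    frame, classifies unitary gene losses, screens for convergent losses
    associated with a binary phenotype via phylogenetic generalized least
    squares, dates losses from Ka/Ks on the loss branch, and validates
    candidate mutations against unassembled sequencing reads. Includes a
    seeded synthetic-evolution generator that produces truth-labelled
    genomes, annotations, alignments, trees, and reads so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    nlme,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
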