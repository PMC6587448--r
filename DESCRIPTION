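Package: panforge
Title: Pan-Genome Construction and Molecular-Evolution Screens for Multi-Variety Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing a plant pan-genome from several
    varieties of one species: reference-assisted scaffolding of draft
    assemblies, evidence-based refinement of predicted gene sets, Markov
    clustering of all-vs-all protein similarity graphs into ortholog families,
    core/dispensable classification of gene families and genome regions,
    tandem- and whole-genome-duplication origin labelling via adjacency and
    collinear block chaining, single-copy-family phylogeny with
    fourfold-degenerate-site strict-clock dating, and a codon-model (GY94)
    selection scan with branch and branch-site likelihood-ratio tests under
    FDR control. A synthetic-data generator produces multi-variety genomes
    with planted core/dispensable family structure, tandem arrays, duplicated
    blocks and coding sequences evolved under branch-specific dN/dS, so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
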