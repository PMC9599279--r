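Package: votunet
Title: Network-Based Taxonomy Inheritance for Uncultivated Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns ICTV-style taxonomy to viral operational taxonomic
    units (vOTUs) by inheritance from reference phage genomes over a
    weighted gene-sharing similarity network, with confidence-driven
    truncation of the inherited lineage based on clustering status and
    search path. Reads and writes the vConTACT2-style edge list, genome
    overview, and INPHARED-style reference taxonomy formats; computes the
    hypergeometric gene-sharing significance score that defines edge
    weights; exports annotated per-vOTU ego subgraphs for interactive
    viewers; and provides the quantitative report layer (miner-overlap
    combination counts, reads-per-million normalization, alpha and beta
    diversity, per-rank taxonomy summaries). Includes a seeded synthetic
    network generator with known ground-truth lineages so the whole
    system can be exercised without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
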