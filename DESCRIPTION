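Package: gvpipe
Title: Discovery and Characterization of Giant Viruses from Mini-Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used to
    discover nucleocytoplasmic large DNA viruses (NCLDV, "giant viruses") in
    soil metagenomes. Provides marker-based (NCVOG) screening of metagenome
    bins with completeness estimation, dereplication of genomes by average
    nucleotide identity (ANI), phylogenetic-diversity accounting on marker
    trees, the major capsid protein (MCP) survey filter cascade, orthogroup
    gene-sharing networks, and a stochastic simulator of FACS-sorted
    mini-metagenomics with multiple displacement amplification (MDA) bias
    that doubles as a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
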