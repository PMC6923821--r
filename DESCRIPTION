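Package: splitgraphr
Title: Split-Graph Analysis of Microbial Co-Occurrence and Functional
    Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds FDR-controlled Spearman co-occurrence networks from
    taxon abundance tables, scores taxon-to-KEGG-module associations by
    the fraction of module KOs correlated with each taxon (KO density),
    assembles split graphs whose clique side holds correlated taxa and
    whose independent side holds functional modules, extracts
    high-weighted maximal cliques, and compares groups by the proportion
    of correlated edges sharing a taxonomic ancestor using a pooled
    two-proportion z-test. Includes a synthetic-data generator with
    planted correlation blocks and taxon-to-module couplings, TSV/GraphML
    export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
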