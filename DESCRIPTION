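Package: fruitwalk
Title: Network Propagation for Prioritizing Fruit-Related Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate genes by random walk with restart on a
    weighted protein-protein interaction network seeded with validated
    genes, screens the resulting propagation scores against an empirical
    null built from randomly resampled seed sets, and applies two
    guilt-by-association linkage filters: the maximum interaction score
    against any seed and the maximum cosine similarity of functional
    annotation vectors. Includes readers for STRING-style weighted links,
    OBO ontologies and gene/annotation tables, and a planted-module
    synthetic benchmark generator so that every stage of the pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
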