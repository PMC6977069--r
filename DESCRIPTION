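Package: segnet
Title: Segregation Analysis of Plankton Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Ocean", "Networks", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Taxon-centric analysis of annotated plankton co-occurrence
    networks ("interactomes"): group-level copresence/exclusion tallies and
    segregator classification, exact binomial exclusion-enrichment tests,
    pairwise-group subnetwork topology (density, degree centralization,
    betweenness, components, diameter), genus- and barcode-level
    connectivity and biogeography profiling, biotic versus abiotic driver
    partitioning, and quantification of the overlap between a curated
    literature interaction database and the network. Ships a seeded
    synthetic-data generator with planted ground truth so every stage is
    testable without external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
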