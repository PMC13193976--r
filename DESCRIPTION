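Package: litkg
Title: Keyword Co-Occurrence Networks, Walktrap Themes, and Biomarker
    Knowledge Graphs from Bibliographic Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A literature-mining pipeline for mapping a biomedical research
    field from bibliographic records. Reads Web of Science tab-delimited and
    PubMed MEDLINE exports, standardizes keyword variants by clustering
    embedding vectors at a cosine-similarity threshold, builds weighted
    keyword co-occurrence networks, detects themes with a from-scratch
    Walktrap community-detection implementation, places themes on a Callon
    strategic diagram (centrality versus density quadrants), and assembles
    subject-predicate-object triples into a knowledge graph whose hub,
    bridge, and emerging nodes are classified from exact centrality
    computations. A synthetic-corpus generator with planted semantic and
    community structure makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    xml2
Config/testthat/edition: 3
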