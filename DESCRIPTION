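Package: dknet
Title: Disease Knowledge Networks as Typed Property Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "maintainer@example.org")
Description: Builds and mines heterogeneous disease-network knowledgebases as
    typed property graphs. Provides an in-memory graph store with a fixed
    protein-centric schema (proteins, diseases, pathways, tissues, drugs and
    gene-expression comparisons joined by sixteen relationship types),
    natural-key deduplication and duplicate-free upserts; importers for
    standard source layouts (reciprocal BLAST hits with sequence-similarity
    scoring, PSI-MITAB 2.5 interactions, curated gene-disease tables,
    drug-target tables, tissue-enhanced expression, pathway membership and
    limma-style differential-expression summaries); disease-context query
    patterns (shared disease proteins, differential-expression network
    neighbourhoods, drug leads through target sequence similarity, and
    bounded all-shortest-paths traversal); deterministic synthetic-data
    generators with planted, independently verified ground truth; and
    exports to JSON-lines, GraphML, bulk-import CSV and Cypher.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
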