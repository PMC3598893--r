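Package: digoverlap
Title: Overlap Survey of Multigenic Disease Groups and Protein Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease groups (DiGs) from OMIM Morbid-Map-style input by
    title normalization and anchored prefix grouping, parses MITAB 2.6
    interaction files in the iRefIndex dialect into binary and bipartite
    (n-ary) records, regenerates spoke-represented protein complexes from
    binary records sharing a database, publication, method and bait, and
    scores DiG overlaps against complexes, pathways and the binary protein
    interaction network with hypergeometric tests, multiple-testing control
    and a degree-matched Monte-Carlo null. Includes a synthetic-data
    generator that emulates all four input formats with a known ground-truth
    manifest, and survey-style reporting (best matches, Venn partitions,
    source-database attribution, Cytoscape exports, cross-run comparison).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
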