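Package: ciliascreen
Title: Multi-Evidence Screen for Multiciliation Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A combined functional-genomics and comparative-genomics screen
    for candidate genes of multiciliated cell differentiation. Filters
    overexpressed genes from differential-expression tables, clusters binary
    overexpression profiles (Jaccard distance, Ward.D2 linkage, dynamic
    hybrid tree cut), classifies clade-contrast differential conservation
    (gene loss and sequence divergence in a focal fish clade), clusters
    phylogenetic presence/absence profiles across a eukaryotic species
    panel, expands candidates through a scored interaction network with
    community detection, performs hypergeometric term-enrichment tests, and
    integrates all evidence layers into a prioritized candidate shortlist.
    Includes a synthetic-data module that generates every pipeline input
    with planted structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
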