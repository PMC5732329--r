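Package: meshindexr
Title: Retrieval-Based Semantic Indexing with Medical Subject Headings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns Medical Subject Headings (MeSH) to biomedical articles by
    vector-space retrieval: documents are indexed as tf-idf weighted term
    vectors, the most cosine-similar indexed documents are retrieved for a
    query article, and the headings of those neighbours are ranked with a
    frequency-and-similarity scoring function and selected by a threshold.
    Includes a MeSH-style thesaurus parser with ancestor, descendant,
    shortest-path and lowest-common-ancestor queries over the tree-number
    forest; the curators' broader-heading replacement rule (three or more
    proposed headings sharing an ancestor are replaced by their lowest common
    ancestor); flat and hierarchical (LCA-based) precision, recall and F
    evaluation; and a synthetic corpus generator in which textual similarity
    predicts label overlap, so the whole pipeline is testable without a
    MEDLINE-scale index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
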