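# meshindexr

Retrieval-based semantic indexing with Medical Subject Headings (MeSH).

Curators index every MEDLINE article with ~12–13 MeSH descriptors drawn
from a thesaurus of tens of thousands of headings. meshindexr implements a
retrieval-based approach for proposing that set automatically, built on the
hypothesis that **similar documents should be indexed by similar
headings**:

1. Index a labeled corpus as tf-idf term vectors,
   `w_{i,d} = tf_{i,d} · ln(|D| / df_i)`, and retrieve the top *X*
   documents for a query article by cosine similarity
   `score(d, q) = V(q)·V(d) / (|V(q)| |V(d)|)`.
2. Collect the retrieved documents' headings (optionally extended with an
   external suggestion list, the role the NLM Medical Text Indexer plays)
   and rank each candidate heading *l* with
   `s(l, q) = tf(l) · Σ_{d: l∈d} score(d, q) / max_{d: l∈d} score(d, q)`,
   keeping those with `s(l, q) > T` (defaults *X* = 10, *T* = 5).
3. Optionally apply the curators' broader-heading rule: three or more
   proposed headings sharing an ancestor in the MeSH tree-number forest
   are replaced by their lowest common ancestor (off by default — it
   trades away recall).
4. Evaluate with flat micro/macro precision, recall and F1, and with
   hierarchical LCA-based variants that give partial credit for
   near-misses in the hierarchy.

The package also ships a MeSH-style thesaurus parser with ancestor /
descendant / shortest-path / LCA queries, a synthetic corpus generator
whose documents' vocabulary is driven by their labels (so the whole
pipeline is testable at desk scale), a parameter-sweep driver, and a thin
command-line interface (`inst/cli/meshindex`) with `index`, `predict`,
`evaluate`, `sweep`, `synth` and `thesaurus-query` subcommands.

## Worked example

```r
library(meshindexr)

# a MeSH-like thesaurus and a corpus whose text is driven by its labels
th    <- generate_thesaurus(seed = 101)           # 640 descriptors, 16 roots
train <- generate_corpus(th, 2000, seed = 102)    # ~12.5 labels/document
test  <- generate_corpus(th, 200,  seed = 103, id_offset = 9000000L)

idx <- build_index(train)
idx
#> A tf-idf retrieval index
#>   documents: 2000
#>   vocabulary: 13300 terms
#>   idf:       ln(|D|/df)
#>   labels/doc: mean 12.45, range [4, 19]

pred <- predict(idx, test, k = 10, threshold = 5)
evaluate_predictions(pred, test, thesaurus = th)
#> Evaluation over 200 documents (micro-averaged flat measures)
#>   precision 0.7162  recall 0.851  F1 0.7778
#>   LCA-P     0.7264  LCA-R  0.8324  LCA-F 0.7758
```

Precision/recall here are flat multilabel measures pooled over the 200 test
documents; LCA-P/R/F score the same predictions after augmenting predicted
and gold sets along hierarchy paths to their lowest common ancestors, so
predicting a correct heading's parent earns partial credit.

Hierarchy queries on the worked thesaurus record shipped with the package
(the heading "Lymphoma", which sits in three branches at once):

```r
fx <- read_thesaurus(system.file("extdata", "mesh_lymphoma.tsv",
                                 package = "meshindexr"))
fx$codes[["D008223"]]
#> [1] "C04.557.386"     "C15.604.515.569" "C20.683.515.761"
sort(unname(fx$name[ancestors(fx, "D008223")]))
#> [1] "Hemic and Lymphatic Diseases"  "Immune System Diseases"
#> [3] "Immunoproliferative Disorders" "Lymphatic Diseases"
#> [5] "Lymphoproliferative Disorders" "Neoplasms"
#> [7] "Neoplasms by Histologic Type"
lowest_common_ancestor(fx, c("D008223", "D008232"))
#> [1] "D008232"   # Lymphoproliferative Disorders
```

See `vignette("retrieval-indexing")` for the model, the generator's
assumptions, and the package's numerical conventions.

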