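---
title: "Retrieval-based MeSH indexing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-based MeSH indexing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Curators index every MEDLINE article with a set of Medical Subject Headings
(MeSH): on average 12–13 descriptors per article, drawn from a thesaurus of
tens of thousands of headings organised in a 16-branch hierarchy. meshindexr
implements a retrieval-based approach to proposing that set automatically.
The working hypothesis is that *similar documents should be indexed by
similar headings*: rather than training one classifier per heading, the
system retrieves the indexed documents most similar to the query article and
transfers their headings.

The retrieval model is the classic vector space model. A document $d$ in a
corpus $D$ is the sparse vector $v_d = [w_{1,d}, \dots, w_{N,d}]$ with

$$ w_{i,d} = \mathrm{tf}_{i,d} \cdot \ln\frac{|D|}{|\{d' \in D : i \in d'\}|}, $$

raw term counts times the unsmoothed log inverse document frequency, and
relevance of $d$ to a query $q$ is the cosine
$\mathrm{score}(d,q) = V(q)\cdot V(d) / (|V(q)|\,|V(d)|)$. `build_index()`
implements exactly this weighting (a `smooth_idf` switch enables the
smoothed variant $\ln\frac{1+|D|}{1+\mathrm{df}} + 1$ for comparison with
common library implementations, and is off by default). Queries are
weighted with the *training* corpus's document frequencies; query terms
unseen at indexing time are ignored. Tokenization lowercases and splits on
every non-alphanumeric character; stopword removal is off by default (a
production search engine would typically remove English stopwords — the
toggle documents that divergence rather than emulating any particular
analyzer).

Given the top $X$ retrieved documents (argument `k`, default 10), every
heading $l$ attached to at least one of them becomes a candidate, scored by

$$ s(l, q) = \mathrm{tf}(l) \cdot
   \frac{\sum_{d : l \in d} \mathrm{score}(d, q)}
        {\max_{d : l \in d} \mathrm{score}(d, q)}, $$

where $\mathrm{tf}(l)$ counts the retrieved documents annotated with $l$.
The normalised similarity sum is scale-free and always at least 1, so
$s(l,q) \ge \mathrm{tf}(l) \ge 1$: a selection threshold $T$ (argument
`threshold`, default 5) below 1 filters nothing, and selection is strictly
antitone in $T$ — raising the threshold can only shrink the prediction,
trading recall for precision. Both defaults correspond to the setting that
maximises F1 in the experiments the method comes from ($X{=}10$, $T{=}5$).

External suggestion lists (the role the NLM Medical Text Indexer plays for
production systems) are consumed as an optional per-document set of
descriptor ids. A suggestion without neighbour support is treated as one
pseudo-supporting document at the maximum hit score, so it scores exactly 1:
it survives any sub-unit threshold and is culled at $T \ge 1$. How such
terms were scored in the original system is unstated; this convention is
the minimal one consistent with "a threshold below 1 applies no filter".

## The thesaurus graph and the broader-heading rule

A descriptor's position in the hierarchy is its set of *tree numbers* —
dot-separated codes such as `C04.557.386` — and one descriptor may sit in
several branches at once. The component-wise proper-prefix relation defines
ancestry; `ancestors()`, `descendants()`, `shortest_path_length()` and
`lowest_common_ancestor()` answer queries over the implied forest. Category
letters themselves (the "C" in `C04`) are not descriptors; depth-1 codes
are the forest's roots.

Two choices the hierarchy leaves genuinely open are fixed as follows:

* **LCA witness rule.** The lowest common ancestor of a set is the
  descriptor owning the *deepest single code* that is a prefix-or-equal of
  some tree number of every member, ties broken by the lexicographically
  smallest code. Requiring one witnessing code makes the result equal to
  pairwise longest-common-prefix enumeration and keeps depth well defined
  when a descriptor spans branches of different depths. A descriptor whose
  members only meet through *different* codes of it is consequently not an
  LCA witness; the broader rule falls back to that shared ancestor itself
  in that (rare) situation.
* **Fixpoint semantics of the broader rule.** The curators' guideline —
  three or more proposed headings sharing an ancestor are replaced by their
  lowest common ancestor — does not say whether it applies once or
  repeatedly, nor in which order. `apply_broader_rule()` fires the deepest
  qualifying group first (most specific replacement), consumes its members
  so one heading joins at most one replacement per pass, and iterates to a
  fixpoint, which is idempotent and terminates because every step removes
  at least `min_group` labels and inserts one. The rule is **off by
  default**: applying it trades away substantial recall (see below), which
  matches the reported experience with real curation data — curators do not
  reliably follow their own guideline.

## Evaluation measures

`flat_prf()` computes multilabel precision/recall/F1, micro-averaged by
default (pooled counts) with a macro (per-document mean) variant, since the
averaging basis of published result tables is often unstated. The
hierarchical measures are a reconstruction of the LCA-based family used by
the BioASQ evaluation: each predicted label is paired with its nearest gold
label by graph distance, the prediction set is augmented with every node on
the tree-number path up to the pair's lowest common ancestor, the gold set
is augmented symmetrically, and LCA-P/LCA-R are the overlap ratios of the
augmented sets, averaged per document, with LCA-F their harmonic mean.
Predicting a parent of the right heading therefore earns partial credit
that an unrelated heading of the same depth does not — the defining
property of hierarchical measures, pinned by golden tests on toy
hierarchies. The full original measure family has additional graph-
construction details (path cost weights, multi-parent flow) that live in
its defining software; this reconstruction is documented as such and pinned
by the package's own golden files rather than claimed equivalent.

## What the synthetic generator emulates

Desk-scale testing cannot use a ten-million-document MEDLINE index, so
`generate_thesaurus()` and `generate_corpus()` build corpora with the one
statistical property the method depends on: *textual similarity predicts
label overlap*.

* **Thesaurus shape.** 16 roots (the number of MeSH categories), full
  ternary subtrees of depth 4 (640 descriptors, mean node depth ≈ 3.6
  against MeSH's reported average of ≈ 4.5 and maximum of 9), and 10% of
  non-root descriptors grafted into a second branch, reproducing the
  multi-parent structure.
* **Label model.** Curated articles on one subject receive largely the same
  headings. Every depth-2 subtree plus its root is a "theme" with a
  canonical heading set (14 descriptors here); a document picks one theme,
  keeps each canonical heading with probability
  `topic_concentration * labels_per_doc_mean / |theme|` (dropout), and adds
  a Poisson remainder drawn uniformly elsewhere, so the label-set mean is
  exactly `labels_per_doc_mean` (default 12.5, the observed per-article
  average; sets are clipped to at least one heading).
* **Text model.** Each descriptor owns a disjoint 20-word signature
  vocabulary; each of 150 word draws comes from a uniformly chosen document
  label's signature, or — with probability `noise_rate` — from a shared
  500-word background vocabulary. Sampling with replacement makes raw term
  frequency informative, exercising the tf component of the weighting.

What this deliberately does *not* emulate: natural biomedical language
(synonymy, morphology, collocations), realistic journal metadata, label
frequency skew, or MEDLINE's scale. Passing end-to-end tests on these
corpora demonstrates that the pipeline's machinery recovers label structure
when the core assumption holds and degrades gracefully when it is
destroyed; it does not certify performance on real abstracts.

At the study conditions used in the tests and the acceptance script (2,000
training and 200 test documents, noise 0.1, defaults elsewhere) the default
pipeline reaches micro-F1 ≈ 0.75–0.78 depending on seed. Because term
weighting already down-weights the high-frequency background vocabulary,
performance is insensitive to noise until the signal share becomes very
small, then collapses: the degradation check therefore probes noise rates
{0.1, 0.9, 0.95, 1.0}, and at `noise_rate = 1` (text independent of labels)
F1 falls to the random-neighbour baseline (< 0.01). Applying the broader
rule on these corpora collapses theme-mates into their shared subtree root
and costs most of the recall — directionally the reported effect of the
rule, amplified by the generator's concentrated label sets.

## Numerical and degenerate-case conventions

* A one-document corpus has every idf, hence every weight, equal to zero;
  zero-norm vectors are defined to have similarity 0 (flagged with a
  warning) so batch runs stay total.
* Retrieval ties are broken by ascending document id; label-score ties by
  ascending descriptor id; LCA ties by smallest tree number — every stage
  is deterministic given its inputs.
* If every supporting score of a candidate is zero (possible only when `k`
  exceeds the number of matching documents), the normalised sum is taken at
  its limiting value $\mathrm{tf}$, scoring $\mathrm{tf}^2$.
* A replacement heading introduced by the broader rule inherits the maximum
  score of the headings it replaced, keeping the output ranking total.
* Selection uses the strict inequality $s(l,q) > T$.
* File writes go through a temporary file renamed into place, so
  interrupted runs never leave truncated outputs; serialization uses full
  double precision, making index and corpus round-trips exact and repeated
  writes byte-identical.

## Worked example

```{r, eval = FALSE}
library(meshindexr)

th <- generate_thesaurus(seed = 101)
train <- generate_corpus(th, 2000, seed = 102)
test  <- generate_corpus(th, 200, seed = 103, id_offset = 9000000L)

idx <- build_index(train)
pred <- predict(idx, test, k = 10, threshold = 5)
evaluate_predictions(pred, test, thesaurus = th)
#> Evaluation over 200 documents (micro-averaged flat measures)
#>   precision 0.7162  recall 0.851  F1 0.7778
#>   LCA-P     0.7264  LCA-R  0.8324  LCA-F 0.7758
```

## Known limitations

* The vector space model is the literal printed formulation; it is not a
  BM25-style ranking, and no claim is made that any particular search
  engine's default similarity matches it.
* The LCA measures are a documented reconstruction, not a port of the
  reference evaluation software.
* The thesaurus dialect is the package's own minimal TSV/JSON; official
  MeSH XML/RDF distributions are out of scope.
* In-process retrieval is exact and single-machine; indexing ten million
  documents is out of scope by design.
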