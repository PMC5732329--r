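test_that("candidates aggregate neighbour labels with their scores", {
  hits <- data.frame(doc_id = c("d1", "d2"), score = c(0.9, 0.5))
  store <- list(d1 = c("A", "B"), d2 = "B")
  cand <- collect_candidates(hits, store)
  cand <- cand[order(cand$ui), ]
  expect_equal(cand$ui, c("A", "B"))
  expect_equal(cand$tf, c(1L, 2L))
  expect_equal(cand$supporting_scores, list(0.9, c(0.9, 0.5)))
  expect_equal(cand$tf, lengths(cand$supporting_scores))

  # retrieved document without stored labels is an integrity error
  expect_error(collect_candidates(hits, list(d1 = "A")), "no stored labels")
  # both channels empty violates the precondition
  expect_error(collect_candidates(hits[0, ], store), "at least one")
})

test_that("counting identity: candidate tf sums to total neighbour label count", {
  th <- generate_thesaurus(n_roots = 4, max_depth = 3, seed = 21)
  corp <- generate_corpus(th, 80, words_per_doc = 40, seed = 22)
  idx <- build_index(corp)
  for (i in c(3, 17, 42)) {
    q <- generate_corpus(th, 1, words_per_doc = 40, seed = 22 + i,
                         id_offset = 7000000L)
    hits <- search_index(idx, q, k = 10)
    cand <- collect_candidates(hits, idx$labels)
    expect_equal(sum(cand$tf), sum(lengths(idx$labels[hits$doc_id])))
  }
})

test_that("suggestion-only labels score exactly 1 and duplicates keep neighbour evidence", {
  hits <- data.frame(doc_id = c("d1", "d2"), score = c(0.9, 0.5))
  store <- list(d1 = c("A", "B"), d2 = "B")
  cand <- score_labels(collect_candidates(hits, store, suggestions = c("C", "B")))
  rownames(cand) <- cand$ui
  expect_equal(cand["C", "score"], 1.0)
  expect_true(cand["C", "from_suggestion"])
  expect_true(cand["B", "from_suggestion"])
  expect_equal(cand["B", "tf"], 2L)  # neighbour evidence wins
  # with no hits at all, a suggestion still becomes a unit-score candidate
  c2 <- score_labels(collect_candidates(hits[0, ], store, suggestions = "C"))
  expect_equal(c2$score, 1.0)
  expect_true(c2$from_suggestion)
})

test_that("the scoring function matches its closed forms", {
  mk <- function(scores) {
    data.frame(ui = "A", tf = length(scores), sum_score = sum(scores),
               max_score = max(scores), from_suggestion = FALSE)
  }
  # single support: 1 * s/s = 1 for any s > 0
  for (s in c(0.1, 0.5, 1)) expect_equal(score_labels(mk(s))$score, 1.0)
  # the worked pair: 2 * (1.2 / 0.8) = 3
  expect_equal(score_labels(mk(c(0.8, 0.4)))$score, 3.0)
  # n equal supports score n^2
  for (n in c(2, 5, 10)) {
    expect_equal(score_labels(mk(rep(0.37, n)))$score, n^2)
  }
})

test_that("scores are permutation- and scale-invariant and at least tf", {
  for (seed in 1:20) {
    scores <- with_seed(seed, stats::runif(1 + seed %% 7, 0.05, 1))
    mk <- function(s) data.frame(ui = "A", tf = length(s), sum_score = sum(s),
                                 max_score = max(s), from_suggestion = FALSE)
    base <- score_labels(mk(scores))$score
    expect_equal(score_labels(mk(rev(scores)))$score, base)
    expect_equal(score_labels(mk(scores * 7.3))$score, base)
    expect_gte(base, length(scores))
    expect_gte(base, 1)
  }
})

test_that("selection is strict, sorted, and antitone in the threshold", {
  cand <- score_labels(data.frame(
    ui = c("C", "A", "B"), tf = c(5L, 1L, 2L),
    sum_score = c(2.5, 0.4, 1.2), max_score = c(0.5, 0.4, 0.8),
    from_suggestion = FALSE))
  expect_equal(cand$score[order(cand$ui)], c(1, 3, 25))
  # strict inequality: a candidate at exactly T is dropped
  expect_equal(select_labels(cand, 5)$ui, "C")
  expect_equal(select_labels(cand, 25)$ui, character())
  expect_equal(select_labels(cand, 0)$ui, c("C", "B", "A"))  # score order
  # any threshold below 1 selects every candidate
  expect_equal(nrow(select_labels(cand, 0.999)), nrow(cand))
  # nesting across increasing thresholds
  prev <- select_labels(cand, 0)$ui
  for (th in c(1, 2.9, 3, 10, 30)) {
    cur <- select_labels(cand, th)$ui
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # equal scores are ordered by ascending ui
  tie <- score_labels(data.frame(ui = c("Z", "Y"), tf = c(1L, 1L),
                                 sum_score = c(0.3, 0.6),
                                 max_score = c(0.3, 0.6),
                                 from_suggestion = FALSE))
  expect_equal(select_labels(tie, 0)$ui, c("Y", "Z"))
})

test_that("predicting with one identical neighbour returns its label set", {
  corp <- corpus_frame(c("d1", "d2"),
                       c("lymphoma b cell", "unrelated matter"),
                       c("b cell study", "other things"),
                       labels = list(c("L1", "L2"), c("L3")))
  idx <- build_index(corp)
  q <- corpus_frame("q1", "lymphoma b cell", "b cell study")
  pred <- predict(idx, q, k = 1, threshold = 0)
  expect_setequal(pred$labels[["q1"]]$ui, c("L1", "L2"))
})

test_that("a sub-unit threshold returns the union of neighbour labels plus suggestions", {
  th <- generate_thesaurus(n_roots = 4, max_depth = 3, seed = 31)
  corp <- generate_corpus(th, 60, words_per_doc = 40, seed = 32)
  idx <- build_index(corp)
  q <- generate_corpus(th, 1, words_per_doc = 40, seed = 33,
                       id_offset = 7000000L)
  sugg <- list("7000000" = c("ZZZ1", "ZZZ2"))
  pred <- predict(idx, q, k = 10, threshold = 0.5, suggestions = sugg)
  hits <- search_index(idx, q[1, , drop = FALSE], k = 10)
  expect_setequal(pred$labels[[1]]$ui,
                  union(unlist(idx$labels[hits$doc_id]), c("ZZZ1", "ZZZ2")))
})

test_that("prediction scores are non-increasing with no duplicate labels", {
  th <- generate_thesaurus(n_roots = 4, max_depth = 3, seed = 34)
  corp <- generate_corpus(th, 60, words_per_doc = 40, seed = 35)
  idx <- build_index(corp)
  qs <- generate_corpus(th, 5, words_per_doc = 40, seed = 36,
                        id_offset = 7000000L)
  pred <- predict(idx, qs, k = 10, threshold = 2)
  for (d in pred$labels) {
    expect_false(anyDuplicated(d$ui) > 0)
    expect_true(all(diff(d$score) <= 1e-12))
  }
})

test_that("the broader rule folds grouped predictions into their ancestor", {
  bt <- broader_mini_thesaurus()
  corp <- corpus_frame(
    c("d1", "d2", "d3"),
    c("atm kinase lymphoma", "atm kinase lymphoma", "atm kinase lymphoma"),
    rep("b cell ataxia telangiectasia study", 3),
    labels = list(c("D016393", "D001260", "D008223", "D001402"),
                  c("D016393", "D001260", "D008223", "D006801"),
                  c("D016393", "D001260", "D008223")))
  idx <- build_index(corp)
  q <- corpus_frame("q1", "atm kinase lymphoma",
                    "b cell ataxia telangiectasia study")
  plain <- predict(idx, q, k = 3, threshold = 0)
  folded <- predict(idx, q, k = 3, threshold = 0, thesaurus = bt,
                    apply_rule = TRUE)
  expect_true(all(c("D016393", "D001260", "D008223") %in%
                    plain$labels[[1]]$ui))
  expect_true("D007154" %in% folded$labels[[1]]$ui)
  expect_false(any(c("D016393", "D001260", "D008223") %in%
                     folded$labels[[1]]$ui))
  # the replacement inherits the best score among its members
  expect_equal(folded$labels[[1]]$score[folded$labels[[1]]$ui == "D007154"],
               max(plain$labels[[1]]$score[plain$labels[[1]]$ui %in%
                                             c("D016393", "D001260", "D008223")]))
})
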