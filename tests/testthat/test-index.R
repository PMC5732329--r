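test_that("tokenization lowercases and splits on non-alphanumerics", {
  expect_equal(tokenize("Lymphoma, B-Cell"), c("lymphoma", "b", "cell"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize(NA_character_), character())
  # idempotent under re-joining with spaces
  for (s in c("p53-mediated DNA damage!", "a  b\tc", "X9 alpha-2b")) {
    once <- tokenize(s)
    expect_equal(tokenize(paste(once, collapse = " ")), once)
  }
})

test_that("idf follows ln(|D|/df) including the degenerate single-document corpus", {
  one <- corpus_frame("d1", "alpha beta", "alpha")
  idx1 <- build_index(one)
  expect_true(all(idx1$idf == 0))
  expect_equal(length(idx1$weights@x), 0)  # all-zero vectors stored sparse

  corp <- corpus_frame(sprintf("d%02d", 1:10),
                       rep("common", 10),
                       c("rare", rep("filler", 9)))
  idx <- build_index(corp)
  expect_equal(unname(idx$idf["common"]), 0)        # in all 10 docs
  expect_equal(unname(idx$idf["rare"]), log(10))    # in exactly 1 of 10
  expect_equal(unname(idx$idf["filler"]), log(10 / 9))
})

test_that("duplicate doc_id is rejected at indexing time", {
  corp <- corpus_frame(c("a", "b"), c("x", "y"), c("", ""))
  corp$doc_id <- c("a", "a")
  expect_error(build_index(corp), "duplicate doc_id")
})

test_that("sparse tf-idf weights equal an independent dense computation", {
  th <- generate_thesaurus(n_roots = 6, max_depth = 3, seed = 5)
  corp <- generate_corpus(th, 200, words_per_doc = 60, seed = 6)
  idx <- build_index(corp)
  toks <- lapply(paste(corp$title, corp$abstract), function(s) {
    x <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]; x[nzchar(x)]
  })
  dense <- dense_tfidf_oracle(toks)
  expect_setequal(colnames(dense), idx$vocab)
  expect_equal(as.matrix(idx$weights), unname(dense[, idx$vocab]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cosine similarity matches hand computations and handles zero vectors", {
  v <- c(x = 1, y = 2)
  expect_equal(cosine_similarity(v, v), 1.0)
  expect_equal(cosine_similarity(c(x = 1), c(y = 1)), 0.0)
  expect_equal(cosine_similarity(c(x = 1, y = 2), c(y = 2, z = 1)), 0.8)
  expect_warning(z <- cosine_similarity(numeric(), v), "zero-norm")
  expect_equal(z, 0)
})

test_that("search ranks an identical document first with similarity 1", {
  corp <- corpus_frame(c("d1", "d2", "d3"),
                       c("lymphoma b cell", "cycle arrest", "unrelated terms"),
                       c("b cell study", "mitosis", "something else"),
                       labels = list("A", "B", "C"))
  idx <- build_index(corp)
  q <- corpus_frame("q1", "lymphoma b cell", "b cell study")
  hits <- search_index(idx, q, k = 3)
  expect_equal(hits$doc_id[1], "d1")
  expect_equal(hits$score[1], 1.0, tolerance = 1e-12)
  # k larger than the corpus returns everything, sorted
  expect_equal(nrow(search_index(idx, q, k = 99)), 3)
  expect_true(all(diff(hits$score) <= 1e-12))
  # the query's own doc_id is excluded
  q2 <- corp[1, , drop = FALSE]
  expect_false("d1" %in% search_index(idx, q2, k = 3)$doc_id)
})

test_that("ties in search are broken by ascending doc_id", {
  corp <- corpus_frame(c("d2", "d1", "d3"),
                       c("alpha", "alpha", "beta"), c("", "", ""),
                       labels = list("A", "B", "C"))
  idx <- build_index(corp)
  hits <- search_index(idx, corpus_frame("q", "alpha", ""), k = 3)
  expect_equal(hits$doc_id[1:2], c("d1", "d2"))
})

test_that("top-k retrieval equals exhaustive dense cosine ranking", {
  th <- generate_thesaurus(n_roots = 6, max_depth = 3, seed = 7)
  corp <- generate_corpus(th, 200, words_per_doc = 60, seed = 8)
  queries <- generate_corpus(th, 50, words_per_doc = 60, seed = 9,
                             id_offset = 5000000L)
  idx <- build_index(corp)
  model <- dense_model_oracle(corp)
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, , drop = FALSE]
    got <- search_index(idx, q, k = 10)
    want <- dense_rank_oracle(model, q, k = 10)
    expect_equal(got$doc_id, want$doc_id)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_true(all(diff(got$score) <= 1e-12))  # non-increasing
  }
})

test_that("adding vocabulary-disjoint documents never reorders existing hits", {
  th <- generate_thesaurus(n_roots = 4, max_depth = 3, seed = 10)
  corp <- generate_corpus(th, 60, words_per_doc = 40, seed = 11)
  q <- generate_corpus(th, 1, words_per_doc = 40, seed = 12,
                       id_offset = 5000000L)
  base <- search_index(build_index(corp), q, k = 60)
  extra <- corpus_frame("zzz1", "qqfoo qqbar", "qqbaz qqfoo",
                        labels = list("D000001"))
  grown <- rbind(corp, extra)
  class(grown) <- class(corp)
  after <- search_index(build_index(grown), q, k = 61)
  expect_equal(setdiff(after$doc_id, "zzz1"), base$doc_id)
})

test_that("neighbour label overlap beats random documents on coupled corpora", {
  th <- generate_thesaurus(n_roots = 6, max_depth = 3, seed = 13)
  corp <- generate_corpus(th, 150, words_per_doc = 60, noise_rate = 0,
                          seed = 14)
  queries <- generate_corpus(th, 15, words_per_doc = 60, noise_rate = 0,
                             seed = 15, id_offset = 5000000L)
  idx <- build_index(corp)
  gl <- setNames(corp$labels, corp$doc_id)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  top <- rnd <- numeric(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    hits <- search_index(idx, queries[i, , drop = FALSE], k = 10)
    top[i] <- mean(vapply(gl[hits$doc_id], jac, numeric(1),
                          b = queries$labels[[i]]))
    rnd_ids <- with_seed(i, sample(corp$doc_id, 10))
    rnd[i] <- mean(vapply(gl[rnd_ids], jac, numeric(1),
                          b = queries$labels[[i]]))
  }
  expect_gt(mean(top), mean(rnd))
})

test_that("an index persists to JSON and reloads identically", {
  th <- generate_thesaurus(n_roots = 4, max_depth = 3, seed = 16)
  corp <- generate_corpus(th, 40, words_per_doc = 30, seed = 17)
  idx <- build_index(corp)
  f <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f)
  idx2 <- read_index(f)
  expect_equal(idx2$vocab, idx$vocab)
  expect_equal(idx2$df, idx$df)
  expect_equal(idx2$labels, idx$labels)
  expect_equal(as.matrix(idx2$weights), as.matrix(idx$weights),
               tolerance = 1e-15)
  # re-running an unchanged write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
  # reloaded index retrieves identically
  q <- corp[3, , drop = FALSE]
  expect_equal(search_index(idx2, q, k = 5), search_index(idx, q, k = 5))
})

test_that("empty index warns and returns no hits", {
  idx <- build_index(corpus_frame(character(), character(), character()))
  expect_warning(hits <- search_index(idx, corpus_frame("q", "a", "b"), k = 5),
                 "empty index")
  expect_equal(nrow(hits), 0)
})

test_that("smoothed idf variant matches its closed form", {
  corp <- corpus_frame(sprintf("d%d", 1:4), c("a b", "a", "a c", "c"),
                       rep("", 4))
  idx <- build_index(corp, smooth_idf = TRUE)
  expect_equal(unname(idx$idf["a"]), log(5 / 4) + 1)
  expect_equal(unname(idx$idf["b"]), log(5 / 2) + 1)
})
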