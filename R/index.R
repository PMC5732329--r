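# In-process vector-space retrieval: tf-idf weighted inverted index over a
# labeled corpus, queried by cosine similarity. Replaces the search-engine
# stage of the pipeline with an exact, reproducible implementation of the
# printed model: w_{i,d} = tf_{i,d} * ln(|D| / df_i) and
# score(q, d) = V(q).V(d) / (|V(q)| |V(d)|).

#' Tokenize text
#'
#' Lowercases and splits on every non-alphanumeric character; resulting terms
#' contain only `[a-z0-9]`. Deterministic, order-preserving.
#'
#' @param text a character string (length 1; `NA` treated as empty).
#' @return character vector of terms (possibly empty).
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

tokenize_all <- function(texts) {
  texts[is.na(texts)] <- ""
  toks <- strsplit(tolower(texts), "[^a-z0-9]+")
  lapply(toks, function(x) x[nzchar(x)])
}

#' Build a tf-idf inverted index from a labeled corpus
#'
#' The model-fitting step of the pipeline: tokenizes each document (title and
#' abstract concatenated with a single space), computes term weights
#' `tf * ln(|D| / df)` with document frequencies from this corpus, and stores
#' each document's label set for neighbour label transfer. Terms occurring in
#' every document get idf 0 and are dropped from the vectors.
#'
#' @param corpus a `mesh_corpus` data frame ([corpus_frame()]).
#' @param smooth_idf use the smoothed variant `ln((1+|D|)/(1+df)) + 1`
#'   instead of the plain `ln(|D|/df)` (useful for comparison with standard
#'   library implementations).
#' @param stopwords optional character vector of terms to discard.
#' @return an object of class `mesh_index` with `print`, `summary` and
#'   [predict.mesh_index()] methods.
#' @examples
#' corp <- corpus_frame(c("d1", "d2"),
#'                      c("lymphoma study", "cell cycle"),
#'                      c("b cell lymphoma", "cycle arrest"),
#'                      labels = list(c("D008223"), c("D016393")))
#' idx <- build_index(corp)
#' idx
#' @export
build_index <- function(corpus, smooth_idf = FALSE, stopwords = NULL) {
  stopifnot(is.data.frame(corpus))
  doc_id <- as.character(corpus$doc_id)
  if (anyDuplicated(doc_id)) {
    stop("integrity error: duplicate doc_id in corpus: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  text <- paste(corpus$title, corpus$abstract)
  toks <- tokenize_all(text)
  if (length(stopwords)) toks <- lapply(toks, function(x) x[!x %in% stopwords])

  n <- length(doc_id)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocab)) {
    di <- rep.int(seq_len(n), lengths(toks))
    ti <- match(unlist(toks, use.names = FALSE), vocab)
    counts <- Matrix::sparseMatrix(i = di, j = ti, x = 1,
                                   dims = c(n, length(vocab)))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                   dims = c(n, 0L))
  }
  df <- Matrix::colSums(counts > 0)
  idf <- if (smooth_idf) log((1 + n) / (1 + df)) + 1 else log(n / df)
  weights <- Matrix::drop0(counts %*% Matrix::Diagonal(x = idf))
  norms <- sqrt(Matrix::rowSums(weights^2))

  labels <- corpus$labels %||% rep(list(character()), n)
  structure(list(
    doc_ids = doc_id,
    vocab = vocab,
    df = stats::setNames(as.numeric(df), vocab),
    idf = stats::setNames(as.numeric(idf), vocab),
    n_docs = n,
    weights = weights,
    norms = as.numeric(norms),
    labels = stats::setNames(lapply(labels, as.character), doc_id),
    smooth_idf = smooth_idf,
    stopwords = as.character(stopwords %||% character())
  ), class = "mesh_index")
}

#' @export
print.mesh_index <- function(x, ...) {
  cat("A tf-idf retrieval index\n")
  cat("  documents: ", x$n_docs, "\n", sep = "")
  cat("  vocabulary:", length(x$vocab), "terms\n")
  cat("  idf:       ", if (x$smooth_idf) "smoothed ln((1+|D|)/(1+df)) + 1"
      else "ln(|D|/df)", "\n", sep = "")
  nl <- lengths(x$labels)
  if (length(nl)) {
    cat("  labels/doc: mean ", format(round(mean(nl), 2)),
        ", range [", min(nl), ", ", max(nl), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mesh_index <- function(object, ...) {
  nl <- lengths(object$labels)
  structure(list(
    n_docs = object$n_docs,
    n_terms = length(object$vocab),
    n_distinct_labels = length(unique(unlist(object$labels))),
    labels_per_doc = summary(nl),
    nonzero_weights = length(object$weights@x),
    smooth_idf = object$smooth_idf
  ), class = "summary.mesh_index")
}

#' @export
print.summary.mesh_index <- function(x, ...) {
  cat("tf-idf retrieval index:", x$n_docs, "documents,", x$n_terms, "terms,",
      x$nonzero_weights, "non-zero weights\n")
  cat("distinct labels:", x$n_distinct_labels, "\n")
  cat("labels per document:\n")
  print(x$labels_per_doc)
  invisible(x)
}

#' Term weights of a document under an index's idf table
#'
#' Queries are weighted with the document frequencies of the training corpus
#' only; query terms outside the index vocabulary are ignored.
#'
#' @param index a `mesh_index`.
#' @param doc one-row corpus data frame, or a character string of raw text.
#' @return named numeric vector of non-zero tf-idf weights.
#' @export
term_weights <- function(index, doc) {
  text <- if (is.character(doc)) paste(doc, collapse = " ")
          else paste(doc$title, doc$abstract)
  toks <- tokenize(text)
  if (length(index$stopwords)) toks <- toks[!toks %in% index$stopwords]
  toks <- toks[toks %in% index$vocab]
  if (!length(toks)) return(stats::setNames(numeric(), character()))
  tf <- table(toks)
  w <- as.numeric(tf) * unname(index$idf[names(tf)])
  keep <- w != 0
  stats::setNames(as.numeric(w[keep]), names(tf)[keep])
}

#' Cosine similarity between two sparse term-weight vectors
#'
#' `dot(a, b) / (||a|| ||b||)` over the union of the two supports. A zero or
#' empty vector yields similarity 0 (flagged with a warning) rather than an
#' error, so degenerate documents keep batch runs total.
#'
#' @param a,b named numeric vectors (term -> weight).
#' @return a number in `[0, 1]` for non-negative weights.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm vector: similarity defined as 0", call. = FALSE)
    return(0)
  }
  shared <- intersect(names(a), names(b))
  sum(a[shared] * b[shared]) / (na * nb)
}

#' Retrieve the most similar indexed documents
#'
#' Ranks every indexed document by cosine similarity to the query and returns
#' the top `k`. A document whose `doc_id` equals the query's is excluded
#' (self-match guard for cross-validation style runs). Ties are broken by
#' ascending `doc_id`; documents or queries with zero-norm vectors score 0.
#'
#' @param index a `mesh_index`.
#' @param query_doc one-row corpus data frame (its `labels`, if any, are
#'   ignored) or a raw text string.
#' @param k number of documents to retrieve (`k >= 1`); capped at the corpus
#'   size.
#' @return data frame with columns `doc_id` and `score`, sorted by score
#'   descending.
#' @export
search_index <- function(index, query_doc, k = 10) {
  stopifnot(inherits(index, "mesh_index"), k >= 1)
  if (index$n_docs == 0L) {
    warning("empty index: no documents to retrieve", call. = FALSE)
    return(data.frame(doc_id = character(), score = numeric()))
  }
  qw <- term_weights(index, query_doc)
  qn <- sqrt(sum(qw^2))
  if (qn == 0) {
    scores <- rep(0, index$n_docs)
  } else {
    qv <- Matrix::sparseVector(x = unname(qw),
                               i = match(names(qw), index$vocab),
                               length = length(index$vocab))
    dots <- as.numeric(index$weights %*% qv)
    scores <- dots / (index$norms * qn)
    scores[!is.finite(scores)] <- 0
  }
  keep <- rep(TRUE, index$n_docs)
  if (!is.character(query_doc) && !is.null(query_doc$doc_id)) {
    keep <- index$doc_ids != as.character(query_doc$doc_id)
  }
  ids <- index$doc_ids[keep]
  sc <- scores[keep]
  ord <- order(-sc, ids)
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(doc_id = ids[top], score = sc[top], stringsAsFactors = FALSE)
}

#' Persist an index to a portable JSON container
#'
#' Stores the document-frequency table, the sparse tf-idf vectors (as
#' triplets, full double precision) and the per-document label sets, so a
#' reloaded index is identical to the original in-memory object.
#'
#' @param index a `mesh_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  trip <- Matrix::mat2triplet(index$weights)
  obj <- list(
    format = "mesh_index",
    version = 1L,
    smooth_idf = index$smooth_idf,
    stopwords = index$stopwords,
    n_docs = index$n_docs,
    doc_ids = index$doc_ids,
    vocab = index$vocab,
    df = unname(index$df),
    triplets = list(i = trip$i, j = trip$j, x = trip$x),
    labels = index$labels
  )
  atomic_write(path, function(p) {
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  })
}

#' Load an index written by [write_index()]
#'
#' @param path path to the index JSON container.
#' @return a `mesh_index`.
#' @export
read_index <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mesh_index")) {
    stop("not a mesh_index container: ", path, call. = FALSE)
  }
  n <- as.integer(obj$n_docs)
  vocab <- as.character(obj$vocab %||% character())
  df <- as.numeric(obj$df %||% numeric())
  idf <- if (isTRUE(obj$smooth_idf)) log((1 + n) / (1 + df)) + 1 else log(n / df)
  weights <- Matrix::sparseMatrix(i = as.integer(unlist(obj$triplets$i)),
                                  j = as.integer(unlist(obj$triplets$j)),
                                  x = as.numeric(unlist(obj$triplets$x)),
                                  dims = c(n, length(vocab)))
  labels <- obj$labels
  if (is.character(labels)) labels <- as.list(labels)
  labels <- lapply(labels, as.character)
  structure(list(
    doc_ids = as.character(obj$doc_ids),
    vocab = vocab,
    df = stats::setNames(df, vocab),
    idf = stats::setNames(as.numeric(idf), vocab),
    n_docs = n,
    weights = weights,
    norms = as.numeric(sqrt(Matrix::rowSums(weights^2))),
    labels = labels,
    smooth_idf = isTRUE(obj$smooth_idf),
    stopwords = as.character(obj$stopwords %||% character())
  ), class = "mesh_index")
}
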