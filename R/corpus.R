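# Labeled-document corpora in the BioASQ-style JSON dialect:
# {"documents": [{"pmid": ..., "title": ..., "abstractText": ...,
#   "journal": ..., "year": ..., "meshMajor": [...]}, ...]}

#' Construct a labeled corpus
#'
#' A corpus is a data frame with one row per article: `doc_id` (PMID role),
#' `title`, `abstract`, optional `journal` and `year`, and a list column
#' `labels` of descriptor uis (the gold MeSH annotation; empty for unlabeled
#' query documents).
#'
#' @param doc_id,title,abstract character vectors of equal length.
#' @param labels list of character vectors (one per document), or `NULL`.
#' @param journal,year optional metadata vectors.
#' @return a data frame of class `mesh_corpus`.
#' @export
corpus_frame <- function(doc_id, title, abstract, labels = NULL,
                         journal = NULL, year = NULL) {
  doc_id <- as.character(doc_id)
  n <- length(doc_id)
  if (anyDuplicated(doc_id)) {
    stop("integrity error: duplicate doc_id: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  labels <- labels %||% rep(list(character()), n)
  stopifnot(length(title) == n, length(abstract) == n, length(labels) == n)
  out <- data.frame(doc_id = doc_id,
                    title = as.character(title),
                    abstract = as.character(abstract),
                    journal = if (is.null(journal)) rep(NA_character_, n)
                              else as.character(journal),
                    year = if (is.null(year)) rep(NA_integer_, n)
                           else as.integer(year),
                    stringsAsFactors = FALSE)
  out$labels <- lapply(labels, as.character)
  class(out) <- c("mesh_corpus", "data.frame")
  out
}

#' Read a corpus JSON file
#'
#' Reads the BioASQ-style dialect. `meshMajor` entries may be descriptor uis
#' or heading names; names are resolved against `thesaurus` when one is
#' supplied, and unresolvable entries raise an error (or a warning with
#' `on_unresolved = "warn"`).
#'
#' @param path path to a corpus JSON file.
#' @param thesaurus optional `mesh_thesaurus` used to resolve heading names.
#' @param on_unresolved `"error"` or `"warn"` (warn drops the entry).
#' @return a `mesh_corpus` data frame.
#' @export
read_corpus <- function(path, thesaurus = NULL,
                        on_unresolved = c("error", "warn")) {
  on_unresolved <- match.arg(on_unresolved)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("corrupt corpus JSON at ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  docs <- obj$documents %||% obj
  if (!length(docs)) {
    return(corpus_frame(character(), character(), character()))
  }
  get_chr <- function(d, key, i, required = FALSE) {
    v <- d[[key]]
    if (is.null(v)) {
      if (required) stop("corrupt corpus JSON: record ", i, " lacks key '",
                         key, "'", call. = FALSE)
      return(NA_character_)
    }
    as.character(v)
  }
  doc_id <- vapply(seq_along(docs), function(i) get_chr(docs[[i]], "pmid", i, TRUE),
                   character(1))
  title <- vapply(seq_along(docs), function(i) {
    v <- get_chr(docs[[i]], "title", i); if (is.na(v)) "" else v
  }, character(1))
  abstract <- vapply(seq_along(docs), function(i) {
    v <- get_chr(docs[[i]], "abstractText", i); if (is.na(v)) "" else v
  }, character(1))
  journal <- vapply(seq_along(docs), function(i) get_chr(docs[[i]], "journal", i),
                    character(1))
  year <- vapply(docs, function(d) {
    if (is.null(d$year)) NA_integer_ else as.integer(d$year)
  }, integer(1))
  labels <- lapply(seq_along(docs), function(i) {
    raw <- as.character(unlist(docs[[i]]$meshMajor))
    resolve_labels(raw, thesaurus, on_unresolved, doc_id[i])
  })
  corpus_frame(doc_id, title, abstract, labels, journal, year)
}

# Map meshMajor entries (uis or heading names) to descriptor uis.
resolve_labels <- function(raw, thesaurus, on_unresolved, doc_id) {
  if (!length(raw) || is.null(thesaurus)) return(unique(raw))
  name_to_ui <- stats::setNames(names(thesaurus$name), unname(thesaurus$name))
  out <- ifelse(raw %in% thesaurus$ui, raw,
                unname(name_to_ui[raw]))
  bad <- raw[is.na(out)]
  if (length(bad)) {
    msg <- paste0("document ", doc_id, ": unresolvable meshMajor entries: ",
                  paste(bad, collapse = ", "))
    if (on_unresolved == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  unique(out[!is.na(out)])
}

#' Write a corpus JSON file
#'
#' @param corpus a `mesh_corpus` (or compatible data frame).
#' @param path output path.
#' @param thesaurus optional; when given, labels are written as heading names
#'   instead of uis.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, thesaurus = NULL) {
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    labs <- corpus$labels[[i]]
    if (!is.null(thesaurus) && length(labs)) labs <- unname(thesaurus$name[labs])
    d <- list(pmid = corpus$doc_id[i],
              title = corpus$title[i],
              abstractText = corpus$abstract[i])
    if (!is.na(corpus$journal[i])) d$journal <- corpus$journal[i]
    if (!is.na(corpus$year[i])) d$year <- corpus$year[i]
    d$meshMajor <- as.list(labs)
    d
  })
  atomic_write(path, function(p) {
    jsonlite::write_json(list(documents = docs), p, auto_unbox = TRUE,
                         digits = NA)
  })
}

# Named list doc_id -> character vector of gold uis.
gold_labels <- function(corpus) {
  stats::setNames(corpus$labels, corpus$doc_id)
}

#' Read an external suggestions file
#'
#' JSON object mapping doc_id to an array of descriptor uis — the channel an
#' external indexer's (e.g. NLM MTI) proposals arrive through.
#'
#' @param path path to the suggestions JSON.
#' @return named list of character vectors.
#' @export
read_suggestions <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(x) as.character(unlist(x)))
}
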