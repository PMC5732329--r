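# Neighbour-label scoring: candidate headings are collected from the label
# sets of the retrieved documents (optionally extended with external
# suggestions), scored by
#
#   score(l, q) = tf(l) * ( sum_{d : l in d} score(d, q) / max_{d : l in d} score(d, q) )
#
# and selected when score > threshold. tf(l) counts the retrieved documents
# annotated with l; the normalised similarity sum is scale-free and >= 1, so
# every neighbour-supported candidate scores at least 1 and any threshold
# below 1 selects everything.

#' Collect candidate labels from retrieval hits
#'
#' One candidate per distinct descriptor across the retrieved documents'
#' label sets, carrying the count of supporting documents and their cosine
#' scores. Suggestion uis not supported by any neighbour are added as
#' candidates backed by a single pseudo-supporting document whose score
#' equals the maximum hit score, so they score exactly 1; a suggestion that
#' is also neighbour-supported keeps its neighbour evidence and is only
#' flagged.
#'
#' @param hits data frame with columns `doc_id`, `score` ([search_index()]).
#' @param label_store named list mapping doc_id to label uis (e.g.
#'   `index$labels`).
#' @param suggestions optional character vector of externally suggested uis.
#' @return data frame with columns `ui`, `tf`, `sum_score`, `max_score`,
#'   `from_suggestion`, and a list column `supporting_scores`.
#' @export
collect_candidates <- function(hits, label_store, suggestions = NULL) {
  suggestions <- unique(as.character(suggestions %||% character()))
  if (nrow(hits) == 0L && !length(suggestions)) {
    stop("need at least one retrieval hit or one suggestion", call. = FALSE)
  }
  ui <- character(); tf <- integer()
  sum_score <- numeric(); max_score <- numeric()
  supporting <- list()
  if (nrow(hits) > 0L) {
    missing <- setdiff(hits$doc_id, names(label_store))
    if (length(missing)) {
      stop("integrity error: no stored labels for retrieved document(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    labs <- label_store[hits$doc_id]
    all_ui <- unlist(labs, use.names = FALSE)
    if (length(all_ui)) {
      all_sc <- rep.int(hits$score, lengths(labs))
      by_ui <- split(all_sc, all_ui)
      ui <- names(by_ui)
      tf <- lengths(by_ui)
      sum_score <- vapply(by_ui, sum, numeric(1))
      max_score <- vapply(by_ui, max, numeric(1))
      supporting <- unname(by_ui)
    }
  }
  from_suggestion <- ui %in% suggestions
  extra <- setdiff(suggestions, ui)
  if (length(extra)) {
    pseudo <- if (nrow(hits) > 0L) max(hits$score) else 1
    ui <- c(ui, extra)
    tf <- c(tf, rep.int(1L, length(extra)))
    sum_score <- c(sum_score, rep.int(pseudo, length(extra)))
    max_score <- c(max_score, rep.int(pseudo, length(extra)))
    supporting <- c(supporting, rep(list(pseudo), length(extra)))
    from_suggestion <- c(from_suggestion, rep(TRUE, length(extra)))
  }
  out <- data.frame(ui = unname(ui), tf = as.integer(tf),
                    sum_score = unname(sum_score),
                    max_score = unname(max_score),
                    from_suggestion = from_suggestion,
                    stringsAsFactors = FALSE)
  out$supporting_scores <- supporting
  out
}

#' Score candidate labels
#'
#' Applies the ranking function `tf * (sum of supporting scores / max
#' supporting score)` to every candidate. When every supporting score is 0
#' (retrieval returned non-matching documents to fill the requested top-k)
#' the normalised sum is taken at its limiting value `tf`, giving `tf^2`.
#'
#' @param candidates data frame from [collect_candidates()].
#' @return the same data frame with a `score` column added.
#' @export
score_labels <- function(candidates) {
  stopifnot(all(candidates$tf >= 1L))
  ratio <- ifelse(candidates$max_score > 0,
                  candidates$sum_score / candidates$max_score,
                  as.numeric(candidates$tf))
  candidates$score <- candidates$tf * ratio
  candidates
}

#' Select labels above a score threshold
#'
#' Keeps exactly the candidates with `score > threshold` (strict), sorted by
#' score descending with ties broken by ascending ui. Since every supported
#' candidate scores at least 1, any threshold below 1 applies no filter.
#'
#' @param candidates scored candidates ([score_labels()]).
#' @param threshold non-negative score cut-off.
#' @return data frame with columns `ui`, `score` (non-increasing).
#' @export
select_labels <- function(candidates, threshold) {
  stopifnot(threshold >= 0, "score" %in% names(candidates))
  keep <- candidates$score > threshold
  sel <- candidates[keep, c("ui", "score")]
  sel <- sel[order(-sel$score, sel$ui), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

predict_one <- function(index, doc, k, threshold, thesaurus, suggestions,
                        apply_rule, min_group) {
  hits <- search_index(index, doc, k = k)
  cand <- collect_candidates(hits, index$labels, suggestions)
  sel <- select_labels(score_labels(cand), threshold)
  if (apply_rule && nrow(sel) > 0L) {
    res <- apply_broader_rule(sel$ui, thesaurus, min_group = min_group)
    score_of <- stats::setNames(sel$score, sel$ui)
    new_score <- vapply(res$labels, function(u) {
      if (u %in% names(score_of)) unname(score_of[u])
      else {
        # a replacement ancestor inherits the best score of its members
        members <- unlist(lapply(res$replacements, function(r) {
          if (identical(r$replacement, u)) r$members else character()
        }))
        max(score_of[members])
      }
    }, numeric(1))
    sel <- data.frame(ui = res$labels, score = new_score, stringsAsFactors = FALSE)
    sel <- sel[order(-sel$score, sel$ui), , drop = FALSE]
    rownames(sel) <- NULL
  }
  sel
}

#' Predict MeSH labels for new documents
#'
#' End-to-end composition for each query document: retrieve the `k` most
#' cosine-similar indexed documents, collect their labels (plus any external
#' suggestions for that document), score with the frequency-and-similarity
#' ranking function, keep scores above `threshold`, and optionally apply the
#' broader-heading replacement rule. Deterministic given fixed inputs.
#'
#' @param object a `mesh_index` fitted with [build_index()].
#' @param newdata corpus data frame of query documents (labels ignored).
#' @param k number of retrieved documents (the `X` of `Elastic-X-T` settings;
#'   default 10).
#' @param threshold score threshold (the `T` of `Elastic-X-T`; default 5).
#' @param thesaurus `mesh_thesaurus`; required when `apply_rule = TRUE`.
#' @param suggestions named list doc_id -> character vector of suggested uis
#'   ([read_suggestions()]).
#' @param apply_rule apply the broader-heading replacement rule to each
#'   prediction (default `FALSE`: the rule is reported to lower recall).
#' @param min_group minimum number of labels sharing an ancestor for the rule
#'   to fire (default 3).
#' @param ... unused.
#' @return an object of class `mesh_predictions`: a list with `doc_ids` and
#'   `labels` (per-document data frames of `ui`, `score`, sorted by score).
#' @export
predict.mesh_index <- function(object, newdata, k = 10, threshold = 5,
                               thesaurus = NULL, suggestions = NULL,
                               apply_rule = FALSE, min_group = 3, ...) {
  stopifnot(k >= 1, threshold >= 0)
  if (apply_rule && is.null(thesaurus)) {
    stop("apply_rule = TRUE requires a thesaurus", call. = FALSE)
  }
  doc_ids <- as.character(newdata$doc_id)
  labels <- lapply(seq_len(nrow(newdata)), function(i) {
    predict_one(object, newdata[i, , drop = FALSE], k, threshold, thesaurus,
                suggestions[[doc_ids[i]]], apply_rule, min_group)
  })
  structure(list(doc_ids = doc_ids, labels = stats::setNames(labels, doc_ids),
                 k = k, threshold = threshold, apply_rule = apply_rule),
            class = "mesh_predictions")
}

#' @export
print.mesh_predictions <- function(x, ...) {
  nl <- vapply(x$labels, nrow, integer(1))
  cat("MeSH label predictions (k = ", x$k, ", threshold = ", x$threshold,
      if (x$apply_rule) ", broader rule applied", ")\n", sep = "")
  cat("  documents:  ", length(x$doc_ids), "\n", sep = "")
  if (length(nl)) {
    cat("  labels/doc: mean ", format(round(mean(nl), 2)), ", range [",
        min(nl), ", ", max(nl), "]\n", sep = "")
  }
  invisible(x)
}

#' Predicted label sets as a named list
#'
#' @param predictions a `mesh_predictions` object.
#' @return named list doc_id -> character vector of predicted uis.
#' @export
prediction_sets <- function(predictions) {
  lapply(predictions$labels, function(d) d$ui)
}

#' Write predictions to JSON
#'
#' Array of `{"pmid": ..., "labels": [{"ui": ..., "score": ...}]}`; with a
#' thesaurus, a heading `name` field is added to each label.
#'
#' @param predictions a `mesh_predictions`.
#' @param path output path.
#' @param thesaurus optional `mesh_thesaurus` for the names-only variant.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, thesaurus = NULL) {
  docs <- lapply(predictions$doc_ids, function(id) {
    d <- predictions$labels[[id]]
    labs <- lapply(seq_len(nrow(d)), function(i) {
      l <- list(ui = d$ui[i], score = d$score[i])
      if (!is.null(thesaurus)) l$name <- unname(thesaurus$name[d$ui[i]])
      l
    })
    list(pmid = id, labels = labs)
  })
  atomic_write(path, function(p) {
    jsonlite::write_json(docs, p, auto_unbox = TRUE, digits = NA)
  })
}

#' Read predictions written by [write_predictions()]
#'
#' @param path predictions JSON path.
#' @return a `mesh_predictions` object (k/threshold metadata unknown: `NA`).
#' @export
read_predictions <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc_ids <- vapply(obj, function(d) as.character(d$pmid), character(1))
  labels <- lapply(obj, function(d) {
    data.frame(
      ui = vapply(d$labels, function(l) as.character(l$ui), character(1)),
      score = vapply(d$labels, function(l) as.numeric(l$score), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  structure(list(doc_ids = doc_ids, labels = stats::setNames(labels, doc_ids),
                 k = NA, threshold = NA, apply_rule = NA),
            class = "mesh_predictions")
}
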