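# Flat and hierarchical evaluation. Flat precision/recall/F1 follow the
# usual multilabel conventions (micro-averaged by default). The hierarchical
# variants reconstruct LCA-based measures: each predicted label is connected
# to its nearest gold label through their lowest common ancestor and the
# label sets are augmented with the nodes on those paths before precision
# and recall are computed, so near-misses in the hierarchy earn partial
# credit.

as_label_sets <- function(x) {
  if (inherits(x, "mesh_predictions")) return(prediction_sets(x))
  if (is.data.frame(x) && !is.null(x$labels)) return(gold_labels(x))
  stopifnot(is.list(x), !is.null(names(x)))
  lapply(x, function(v) unique(as.character(v)))
}

f_measure <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Flat precision, recall and F1
#'
#' Micro-averaging pools the per-document intersection counts before
#' dividing; macro-averaging takes unweighted means of per-document
#' precision and recall (documents with empty predictions contribute 0).
#' In both cases F1 is the harmonic mean of the reported precision and
#' recall.
#'
#' @param predictions named list doc_id -> predicted uis (or a
#'   `mesh_predictions` object).
#' @param golds named list doc_id -> gold uis (or a `mesh_corpus`); every
#'   predicted document must have a gold set.
#' @param average `"micro"` (default) or `"macro"`.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
flat_prf <- function(predictions, golds, average = c("micro", "macro")) {
  average <- match.arg(average)
  pred <- as_label_sets(predictions)
  gold <- as_label_sets(golds)
  miss <- setdiff(names(pred), names(gold))
  if (length(miss)) {
    stop("missing gold labels for document(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  np <- vapply(pred, length, integer(1))
  ng <- vapply(names(pred), function(id) length(gold[[id]]), integer(1))
  ni <- vapply(names(pred), function(id) length(intersect(pred[[id]], gold[[id]])),
               integer(1))
  if (average == "micro") {
    p <- if (sum(np) == 0) 0 else sum(ni) / sum(np)
    r <- if (sum(ng) == 0) 0 else sum(ni) / sum(ng)
  } else {
    p <- mean(ifelse(np == 0, 0, ni / np))
    r <- mean(ifelse(ng == 0, 0, ni / ng))
  }
  c(precision = p, recall = r, f1 = f_measure(p, r))
}

# Descriptors on the upward tree-number path from `ui` to its ancestor-or-
# self `anc` (both ends included); only codes present in the thesaurus
# contribute nodes.
path_to_ancestor <- function(t, ui, anc) {
  ws <- witness_codes(t, anc)
  # witnessing codes of anc that reach ui
  reach <- ws[vapply(ws, function(w) {
    any(w == t$codes[[ui]]) || any(is_proper_prefix(w, t$codes[[ui]]))
  }, logical(1))]
  if (!length(reach)) return(c(ui, anc))
  d <- code_depth(reach)
  w <- sort(reach[d == max(d)])[1]
  ext <- t$codes[[ui]][w == t$codes[[ui]] | is_proper_prefix(w, t$codes[[ui]])]
  ext <- sort(ext[code_depth(ext) == min(code_depth(ext))])[1]
  chain <- c(code_prefixes(ext), ext)
  chain <- chain[code_depth(chain) >= code_depth(w)]
  nodes <- unname(t$tree_index[chain])
  unique(c(ui, nodes[!is.na(nodes)], anc))
}

augment_sets <- function(t, from, to, dist) {
  # dist: matrix of graph distances, rows = from labels, cols = to labels
  aug <- from
  for (i in seq_along(from)) {
    d <- dist[i, ]
    if (all(!is.finite(d))) next
    nearest <- to[which(d == min(d))]
    nearest <- sort(nearest)[1]
    if (from[i] == nearest) next
    lca <- lowest_common_ancestor(t, c(from[i], nearest))
    if (is.na(lca)) next
    aug <- union(aug, path_to_ancestor(t, from[i], lca))
  }
  aug
}

#' Hierarchical (LCA-based) precision, recall and F
#'
#' For each document, every predicted label is paired with its nearest gold
#' label (graph distance over the tree-number forest); the predicted set is
#' augmented with all nodes on the path from the label up to the pair's
#' lowest common ancestor, and the gold set is augmented symmetrically
#' toward its nearest predicted label. LCA-precision and LCA-recall are the
#' per-document overlap ratios of the augmented sets, averaged (unweighted)
#' over documents; LCA-F is their harmonic mean. A perfect prediction is
#' unaffected by augmentation and scores 1.
#'
#' @inheritParams flat_prf
#' @param t a `mesh_thesaurus` covering all predicted and gold labels.
#' @return named numeric vector `c(lca_p, lca_r, lca_f)`.
#' @export
lca_prf <- function(predictions, golds, t) {
  stopifnot(inherits(t, "mesh_thesaurus"))
  pred <- as_label_sets(predictions)
  gold <- as_label_sets(golds)
  miss <- setdiff(names(pred), names(gold))
  if (length(miss)) {
    stop("missing gold labels for document(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  all_labels <- unique(c(unlist(pred), unlist(gold)))
  check_ui(t, all_labels)
  g <- thesaurus_graph(t)
  ps <- rs <- numeric(length(pred))
  for (i in seq_along(pred)) {
    P <- pred[[i]]; G <- gold[[names(pred)[i]]]
    if (!length(P) || !length(G)) {
      ps[i] <- 0; rs[i] <- 0
      next
    }
    dist <- igraph::distances(g, v = P, to = G)
    aug_p <- augment_sets(t, P, G, dist)
    aug_g <- augment_sets(t, G, P, t(dist))
    ps[i] <- length(intersect(aug_p, aug_g)) / length(aug_p)
    rs[i] <- length(intersect(aug_p, aug_g)) / length(aug_g)
  }
  p <- mean(ps); r <- mean(rs)
  c(lca_p = p, lca_r = r, lca_f = f_measure(p, r))
}

#' Evaluate predictions against gold labels
#'
#' Computes the flat measures and, when a thesaurus is supplied, the
#' hierarchical LCA-based measures.
#'
#' @inheritParams flat_prf
#' @param thesaurus optional `mesh_thesaurus` for the hierarchical measures.
#' @return an object of class `mesh_eval`: precision, recall, f1, lca_p,
#'   lca_r, lca_f (NA without a thesaurus), n_documents, average.
#' @export
evaluate_predictions <- function(predictions, golds, thesaurus = NULL,
                                 average = c("micro", "macro")) {
  average <- match.arg(average)
  flat <- flat_prf(predictions, golds, average = average)
  lca <- c(lca_p = NA_real_, lca_r = NA_real_, lca_f = NA_real_)
  if (!is.null(thesaurus)) lca <- lca_prf(predictions, golds, thesaurus)
  structure(list(
    precision = unname(flat["precision"]),
    recall = unname(flat["recall"]),
    f1 = unname(flat["f1"]),
    lca_p = unname(lca["lca_p"]),
    lca_r = unname(lca["lca_r"]),
    lca_f = unname(lca["lca_f"]),
    n_documents = length(as_label_sets(predictions)),
    average = average
  ), class = "mesh_eval")
}

#' @export
print.mesh_eval <- function(x, digits = 4, ...) {
  cat("Evaluation over ", x$n_documents, " documents (",
      x$average, "-averaged flat measures)\n", sep = "")
  cat("  precision ", format(round(x$precision, digits)),
      "  recall ", format(round(x$recall, digits)),
      "  F1 ", format(round(x$f1, digits)), "\n", sep = "")
  if (!is.na(x$lca_p)) {
    cat("  LCA-P     ", format(round(x$lca_p, digits)),
        "  LCA-R  ", format(round(x$lca_r, digits)),
        "  LCA-F ", format(round(x$lca_f, digits)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.mesh_eval <- function(x, ...) {
  data.frame(precision = x$precision, recall = x$recall, f1 = x$f1,
             lca_p = x$lca_p, lca_r = x$lca_r, lca_f = x$lca_f,
             n_documents = x$n_documents, average = x$average,
             stringsAsFactors = FALSE)
}

#' Write an evaluation report to JSON
#'
#' @param eval a `mesh_eval` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval <- function(eval, path) {
  atomic_write(path, function(p) {
    jsonlite::write_json(unclass(eval), p, auto_unbox = TRUE, digits = NA)
  })
}
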