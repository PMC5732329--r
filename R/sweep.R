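# Parameter-grid experiment driver: evaluates the pipeline for every
# combination of k (retrieved documents) and threshold, the experiment grid
# behind the precision/recall trade-off. Retrieval and candidate scoring are
# done once per k; re-thresholding is a cheap filter.

#' Sweep the retrieval depth and score threshold
#'
#' @param index a `mesh_index`.
#' @param queries corpus data frame of query documents.
#' @param golds gold label sets (named list or labeled `mesh_corpus`).
#' @param thesaurus optional `mesh_thesaurus` (adds the LCA measures and is
#'   required for `apply_rule`).
#' @param k_values,threshold_values non-empty numeric vectors of grid values.
#' @param suggestions optional named list of per-document suggested uis.
#' @param apply_rule apply the broader-heading rule in every cell.
#' @param average flat-measure averaging mode.
#' @return data frame with one row per grid cell: `setting` (the
#'   `Elastic-X-T` style row label), `k`, `threshold`, `mean_labels`,
#'   `precision`, `recall`, `f1`, `lca_p`, `lca_r`, `lca_f`.
#' @export
sweep_grid <- function(index, queries, golds, thesaurus = NULL,
                       k_values = c(10, 20, 30, 40, 50),
                       threshold_values = c(0, 1.5, 2.5, 4, 5, 6, 7, 8, 9),
                       suggestions = NULL, apply_rule = FALSE,
                       average = c("micro", "macro")) {
  average <- match.arg(average)
  stopifnot(length(k_values) >= 1, length(threshold_values) >= 1)
  doc_ids <- as.character(queries$doc_id)
  rows <- list()
  for (k in k_values) {
    scored <- lapply(seq_len(nrow(queries)), function(i) {
      hits <- search_index(index, queries[i, , drop = FALSE], k = k)
      score_labels(collect_candidates(hits, index$labels,
                                      suggestions[[doc_ids[i]]]))
    })
    for (th in threshold_values) {
      sets <- lapply(seq_along(scored), function(i) {
        sel <- select_labels(scored[[i]], th)
        if (apply_rule && nrow(sel) > 0L) {
          apply_broader_rule(sel$ui, thesaurus)$labels
        } else {
          sel$ui
        }
      })
      names(sets) <- doc_ids
      ev <- evaluate_predictions(sets, golds, thesaurus = thesaurus,
                                 average = average)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = sprintf("Elastic-%g-%g", k, th),
        k = k, threshold = th,
        mean_labels = mean(lengths(sets)),
        precision = ev$precision, recall = ev$recall, f1 = ev$f1,
        lca_p = ev$lca_p, lca_r = ev$lca_r, lca_f = ev$lca_f,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep table as TSV
#'
#' Column layout mirrors the experiment tables: setting label, flat P/R/F1,
#' then the LCA measures.
#'
#' @param sweep data frame from [sweep_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  atomic_write(path, function(p) {
    utils::write.table(sweep, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
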