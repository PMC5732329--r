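# The curators' "Specific Headings vs Broader Headings" heuristic: when 3 or
# more headings proposed for one article share a common ancestor, replace
# them with their lowest common ancestor. Implemented as a fixpoint: the
# deepest qualifying group fires first, its members are consumed, and the
# reduced set is re-examined until no group remains.

#' Find groups of labels sharing a common ancestor
#'
#' For every descriptor that is a proper ancestor of at least `min_group` of
#' the given labels, returns the group of those labels together with their
#' lowest common ancestor (which may lie deeper than the shared ancestor).
#' Groups are sorted by ancestor depth descending, ties by the ancestor's
#' lexicographically smallest tree number.
#'
#' @param labels character vector of descriptor uis.
#' @param t a `mesh_thesaurus`.
#' @param min_group minimum group size (default 3, the curators' rule).
#' @param on_missing `"error"` (default) or `"skip"` (drop labels absent from
#'   the thesaurus with a warning).
#' @return list of groups, each a list with elements `ancestor`, `members`,
#'   `replacement` (the members' LCA, falling back to the shared ancestor
#'   when the members only meet through different branches of it) and
#'   `depth`.
#' @export
find_broader_groups <- function(labels, t, min_group = 3,
                                on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(t, "mesh_thesaurus"), min_group >= 2)
  labels <- unique(as.character(labels))
  unknown <- setdiff(labels, t$ui)
  if (length(unknown)) {
    if (on_missing == "error") stop_unknown_ui(unknown)
    warning("skipping labels absent from thesaurus: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    labels <- setdiff(labels, unknown)
  }
  if (length(labels) < min_group) return(list())

  anc_of <- lapply(labels, function(l) ancestors(t, l))
  members_of <- split(rep(labels, lengths(anc_of)),
                      unlist(anc_of, use.names = FALSE))
  members_of <- members_of[lengths(members_of) >= min_group]
  if (!length(members_of)) return(list())

  groups <- lapply(names(members_of), function(a) {
    members <- sort(unique(members_of[[a]]))
    lca <- lowest_common_ancestor(t, members)
    list(ancestor = a,
         members = members,
         replacement = if (is.na(lca)) a else lca,
         depth = descriptor_depth(t, a))
  })
  depth <- vapply(groups, `[[`, numeric(1), "depth")
  min_code <- vapply(groups, function(g) sort(t$codes[[g$ancestor]])[1],
                     character(1))
  groups[order(-depth, min_code)]
}

#' Apply the broader-heading replacement rule
#'
#' Iteratively replaces the deepest group of `min_group` or more labels
#' sharing a common ancestor by their lowest common ancestor, until no such
#' group remains. Each step removes at least `min_group` labels and inserts
#' one, so the result never grows and the procedure terminates; the fixpoint
#' is idempotent.
#'
#' @inheritParams find_broader_groups
#' @return list with `labels` (the transformed set, sorted) and
#'   `replacements` (one entry per fired group: `members`, `replacement`).
#' @export
apply_broader_rule <- function(labels, t, min_group = 3,
                               on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  current <- unique(as.character(labels))
  unknown <- setdiff(current, t$ui)
  if (length(unknown)) {
    if (on_missing == "error") stop_unknown_ui(unknown)
    warning("labels absent from thesaurus pass through untouched: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    current <- setdiff(current, unknown)
  }
  replacements <- list()
  repeat {
    groups <- find_broader_groups(current, t, min_group = min_group)
    if (!length(groups)) break
    g <- groups[[1]]
    n_before <- length(current)
    current <- union(setdiff(current, g$members), g$replacement)
    replacements[[length(replacements) + 1L]] <-
      list(members = g$members, replacement = g$replacement)
    stopifnot(length(current) < n_before)  # termination guard
  }
  list(labels = sort(c(current, unknown)), replacements = replacements)
}
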