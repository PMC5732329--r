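# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's index/graph machinery: dense matrices, explicit prefix
# enumeration and hand-rolled BFS, so agreement is a real cross-check.

lymphoma_thesaurus <- function() {
  read_thesaurus(system.file("extdata", "mesh_lymphoma.tsv",
                             package = "meshindexr"))
}

broader_mini_thesaurus <- function() {
  read_thesaurus(system.file("extdata", "broader_mini_synthetic.tsv",
                             package = "meshindexr"))
}

# --- thesaurus oracles -------------------------------------------------------

split_code_o <- function(code) strsplit(code, ".", fixed = TRUE)[[1]]

# is `a` a proper component-level prefix of `b`?
proper_prefix_o <- function(a, b) {
  pa <- split_code_o(a); pb <- split_code_o(b)
  length(pa) < length(pb) && identical(pa, pb[seq_along(pa)])
}

# proper ancestors by brute-force enumeration over all code pairs
ancestors_oracle <- function(t, ui) {
  out <- character()
  for (v in t$ui) {
    if (v == ui) next
    hit <- any(vapply(t$codes[[v]], function(cv) {
      any(vapply(t$codes[[ui]], function(cu) proper_prefix_o(cv, cu),
                 logical(1)))
    }, logical(1)))
    if (hit) out <- c(out, v)
  }
  out
}

# LCA by enumeration of every existing code that is prefix-or-equal of some
# code of every input; deepest wins, ties by smallest code
lca_oracle <- function(t, uis) {
  all_codes <- names(t$tree_index)
  ok <- vapply(all_codes, function(w) {
    all(vapply(uis, function(u) {
      any(vapply(t$codes[[u]], function(cu) {
        w == cu || proper_prefix_o(w, cu)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  cand <- all_codes[ok]
  if (!length(cand)) return(NA_character_)
  d <- lengths(strsplit(cand, ".", fixed = TRUE))
  unname(t$tree_index[sort(cand[d == max(d)])[1]])
}

# hand-rolled BFS over the explicit parent/child edge list
bfs_oracle <- function(t, from, to) {
  if (from == to) return(0)
  edges <- list()
  for (code in names(t$tree_index)) {
    parts <- split_code_o(code)
    if (length(parts) < 2) next
    parent <- paste(parts[-length(parts)], collapse = ".")
    if (parent %in% names(t$tree_index)) {
      edges[[length(edges) + 1L]] <- c(unname(t$tree_index[parent]),
                                       unname(t$tree_index[code]))
    }
  }
  adj <- new.env()
  for (e in edges) {
    assign(e[1], union(mget(e[1], adj, ifnotfound = list(character()))[[1]], e[2]), adj)
    assign(e[2], union(mget(e[2], adj, ifnotfound = list(character()))[[1]], e[1]), adj)
  }
  dist <- stats::setNames(rep(Inf, length(t$ui)), t$ui)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in mget(u, adj, ifnotfound = list(character()))[[1]]) {
      if (!is.finite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  unname(dist[to])
}

# --- retrieval oracles -------------------------------------------------------

# dense tf-idf over a token list, plain ln(|D|/df) weighting
dense_tfidf_oracle <- function(token_lists) {
  vocab <- sort(unique(unlist(token_lists)))
  n <- length(token_lists)
  tf <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    tab <- table(token_lists[[i]])
    tf[i, names(tab)] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  tf * matrix(log(n / df), n, length(vocab), byrow = TRUE)
}

# exhaustive dense cosine ranking, replicating the contracts
# (training-corpus idf, self-exclusion, tie-break on ascending doc_id);
# the dense model is built once, then queried per document
dense_model_oracle <- function(corpus) {
  toks <- lapply(paste(corpus$title, corpus$abstract), function(s) {
    x <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]; x[nzchar(x)]
  })
  W <- dense_tfidf_oracle(toks)
  dfreq <- colSums(W != 0)
  # recompute df independently of the weight matrix (idf-0 columns are all
  # zero in W, so patch those from the raw token lists)
  zero <- which(dfreq == 0)
  for (j in zero) {
    dfreq[j] <- sum(vapply(toks, function(tk) colnames(W)[j] %in% tk,
                           logical(1)))
  }
  list(W = W, dfreq = dfreq, n = nrow(W), doc_ids = corpus$doc_id,
       norms = sqrt(rowSums(W^2)))
}

dense_rank_oracle <- function(model, query_doc, k) {
  qt <- strsplit(tolower(paste(query_doc$title, query_doc$abstract)),
                 "[^a-z0-9]+")[[1]]
  qt <- qt[nzchar(qt) & qt %in% colnames(model$W)]
  qv <- stats::setNames(rep(0, ncol(model$W)), colnames(model$W))
  tab <- table(qt)
  if (length(tab)) {
    qv[names(tab)] <- as.numeric(tab) * log(model$n / model$dfreq[names(tab)])
  }
  qn <- sqrt(sum(qv^2))
  scores <- if (qn == 0) rep(0, model$n) else {
    s <- as.numeric(model$W %*% qv) / (model$norms * qn)
    s[!is.finite(s)] <- 0
    s
  }
  keep <- model$doc_ids != query_doc$doc_id
  ids <- model$doc_ids[keep]; sc <- scores[keep]
  ord <- order(-sc, ids)
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(doc_id = ids[top], score = sc[top], stringsAsFactors = FALSE)
}

# --- broader-rule oracle -----------------------------------------------------

# all proper-ancestor sets of a thesaurus, by brute-force enumeration
ancestor_map_oracle <- function(t) {
  stats::setNames(lapply(t$ui, function(u) ancestors_oracle(t, u)), t$ui)
}

# brute-force fixpoint: enumerate every (ancestor, member-subset) pair by
# direct prefix checks, fire the deepest group, repeat
broader_oracle <- function(labels, t, min_group = 3, anc_map = NULL) {
  if (is.null(anc_map)) anc_map <- ancestor_map_oracle(t)
  current <- unique(labels)
  repeat {
    groups <- list()
    for (a in t$ui) {
      members <- sort(Filter(function(l) {
        l != a && a %in% anc_map[[l]]
      }, current))
      if (length(members) >= min_group) {
        lca <- lca_oracle(t, members)
        groups[[length(groups) + 1L]] <- list(
          ancestor = a, members = members,
          replacement = if (is.na(lca)) a else lca,
          depth = max(lengths(strsplit(t$codes[[a]], ".", fixed = TRUE))),
          code = sort(t$codes[[a]])[1])
      }
    }
    if (!length(groups)) break
    depth <- vapply(groups, `[[`, numeric(1), "depth")
    code <- vapply(groups, `[[`, character(1), "code")
    g <- groups[[order(-depth, code)[1]]]
    current <- union(setdiff(current, g$members), g$replacement)
  }
  sort(current)
}

# --- small random fixtures ---------------------------------------------------

small_thesaurus <- function(seed) {
  generate_thesaurus(n_roots = 4, branching_factor = 3, max_depth = 3,
                     multi_parent_frac = 0.25, seed = seed)
}
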