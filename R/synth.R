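# Synthetic thesauri and corpora with the statistical structure the method
# assumes: each descriptor owns a small "signature" vocabulary, each document
# draws a topically coherent label set and writes its words mostly from its
# labels' signatures, so textual similarity predicts label overlap. A
# noise_rate knob replaces signature words with background vocabulary,
# degrading that coupling down to independence at noise_rate = 1.

#' Generate a random MeSH-like thesaurus
#'
#' A forest of `n_roots` full trees of arity `branching_factor` and depth
#' `max_depth` (MeSH-like: 16 category roots, shallow trees). A fraction of
#' non-root descriptors receive a second tree number grafted under a
#' different root, reproducing the multi-parent structure in which one
#' heading appears in several branches. Deterministic given `seed`.
#'
#' @param n_roots number of root descriptors (default 16, the number of MeSH
#'   categories).
#' @param branching_factor children per internal node (default 3).
#' @param max_depth tree depth in levels (default 4; roots are depth 1).
#' @param multi_parent_frac fraction of non-root descriptors given a second
#'   tree number under another root (default 0.1).
#' @param seed integer RNG seed.
#' @return a `mesh_thesaurus`.
#' @export
generate_thesaurus <- function(n_roots = 16, branching_factor = 3,
                               max_depth = 4, multi_parent_frac = 0.1,
                               seed = 1) {
  stopifnot(n_roots >= 1, branching_factor >= 1, max_depth >= 1,
            multi_parent_frac >= 0, multi_parent_frac <= 1)
  with_seed(seed, {
    root_codes <- sprintf("%s01", rep(LETTERS, length.out = n_roots))
    if (n_roots > 26) root_codes <- sprintf("R%03d", seq_len(n_roots))
    codes <- as.list(root_codes)
    root_of <- seq_len(n_roots)
    frontier <- seq_len(n_roots)
    for (lvl in seq_len(max_depth - 1L)) {
      new_frontier <- integer()
      for (p in frontier) {
        kids <- sprintf("%s.%03d", codes[[p]][1], seq_len(branching_factor))
        for (kc in kids) {
          codes[[length(codes) + 1L]] <- kc
          root_of <- c(root_of, root_of[p])
          new_frontier <- c(new_frontier, length(codes))
        }
      }
      frontier <- new_frontier
    }
    n <- length(codes)
    ui <- sprintf("D%06d", seq_len(n))
    name <- sprintf("concept %06d", seq_len(n))

    # second parents: graft under a node belonging to a different root
    depth_of <- code_depth(vapply(codes, `[[`, character(1), 1L))
    non_root <- which(depth_of > 1L)
    n_multi <- round(multi_parent_frac * length(non_root))
    if (n_multi > 0 && n_roots > 1) {
      chosen <- sort(sample(non_root, n_multi))
      for (i in chosen) {
        # keep grafted codes within max_depth
        hosts <- which(root_of != root_of[i] & depth_of < max_depth)
        if (!length(hosts)) next
        h <- hosts[sample.int(length(hosts), 1L)]
        codes[[i]] <- c(codes[[i]],
                        sprintf("%s.%03d", codes[[h]][1], 900 + i %% 100))
      }
      # grafted slots 9xx never collide with the generated 001..b slots, but
      # two grafts under the same host could; drop any duplicate grafts
      all_codes <- unlist(codes)
      dup <- unique(all_codes[duplicated(all_codes)])
      if (length(dup)) {
        codes <- lapply(codes, function(cs) {
          if (length(cs) > 1L && cs[2] %in% dup) cs[1] else cs
        })
      }
    }
    df <- data.frame(ui = ui, name = name, stringsAsFactors = FALSE)
    df$tree_numbers <- codes
    as_thesaurus(df)
  })
}

signature_vocab <- function(ui, size) {
  sprintf("%sx%02d", tolower(ui), seq_len(size))
}

#' Generate a labeled corpus over a thesaurus
#'
#' Label sets are biased toward co-occurring themes, the way curated
#' articles on one subject receive largely the same headings: every depth-2
#' subtree defines a theme whose canonical heading set is the subtree plus
#' its root; each document picks one theme, keeps each canonical heading
#' with a dropout-style inclusion probability (chosen so the expected
#' in-theme share is `topic_concentration` of `labels_per_doc_mean`), and
#' adds a Poisson-distributed remainder of headings drawn uniformly from the
#' rest of the thesaurus, so the total label count has mean
#' `labels_per_doc_mean` (clipped to at least one label). Each of
#' `words_per_doc` word draws comes, with probability `1 - noise_rate`, from
#' the signature vocabulary of a random document label, otherwise from a
#' shared background vocabulary. Deterministic given `seed`.
#'
#' @param t a `mesh_thesaurus` (e.g. from [generate_thesaurus()]).
#' @param n_docs number of documents.
#' @param labels_per_doc_mean mean label-set size (default 12.5, the typical
#'   number of headings per MEDLINE article).
#' @param signature_vocab_size words in each descriptor's signature
#'   vocabulary (default 20).
#' @param words_per_doc words drawn per document (default 150; the first 10
#'   become the title, the rest the abstract).
#' @param noise_rate probability a word comes from the background vocabulary
#'   instead of a label signature (default 0.1).
#' @param topic_concentration expected share of a document's labels coming
#'   from its theme's canonical heading set (default 0.9).
#' @param background_vocab_size size of the shared background vocabulary
#'   (default 500).
#' @param seed integer RNG seed.
#' @param id_offset first doc_id number (lets train/test corpora get
#'   disjoint ids).
#' @return a `mesh_corpus` with gold labels.
#' @export
generate_corpus <- function(t, n_docs, labels_per_doc_mean = 12.5,
                            signature_vocab_size = 20, words_per_doc = 150,
                            noise_rate = 0.1, topic_concentration = 0.9,
                            background_vocab_size = 500, seed = 1,
                            id_offset = 1000000L) {
  stopifnot(inherits(t, "mesh_thesaurus"), n_docs >= 1,
            noise_rate >= 0, noise_rate <= 1,
            labels_per_doc_mean >= 1, words_per_doc >= 1,
            signature_vocab_size >= 1)
  all_codes <- names(t$tree_index)
  depths <- code_depth(all_codes)
  # themes: one per depth-2 node (its subtree plus the root above it); in a
  # one-level thesaurus every root is its own theme
  theme_codes <- all_codes[depths == 2L]
  themes <- if (length(theme_codes)) {
    lapply(theme_codes, function(code) {
      u <- unname(t$tree_index[code])
      root <- unname(t$tree_index[code_prefixes(code)[1]])
      unique(c(root[!is.na(root)], u, descendants(t, u)))
    })
  } else {
    lapply(unique(unname(t$tree_index[depths == 1L])), function(u) u)
  }
  sigs <- lapply(t$ui, function(u) signature_vocab(u, signature_vocab_size))
  names(sigs) <- t$ui
  background <- sprintf("bgword%03d", seq_len(background_vocab_size))

  with_seed(seed, {
    docs <- lapply(seq_len(n_docs), function(i) {
      pool <- themes[[sample.int(length(themes), 1L)]]
      p_incl <- min(1, topic_concentration * labels_per_doc_mean / length(pool))
      labs <- pool[stats::runif(length(pool)) < p_incl]
      n_out <- stats::rpois(1L, max(0, labels_per_doc_mean -
                                         p_incl * length(pool)))
      if (n_out > 0L) {
        rest <- setdiff(t$ui, labs)
        labs <- c(labs, rest[sample.int(length(rest), min(n_out, length(rest)))])
      }
      if (!length(labs)) labs <- pool[sample.int(length(pool), 1L)]
      from_bg <- stats::runif(words_per_doc) < noise_rate
      words <- character(words_per_doc)
      n_bg <- sum(from_bg)
      if (n_bg) {
        words[from_bg] <- background[sample.int(length(background), n_bg,
                                                replace = TRUE)]
      }
      if (n_bg < words_per_doc) {
        src <- labs[sample.int(length(labs), words_per_doc - n_bg,
                               replace = TRUE)]
        words[!from_bg] <- vapply(src, function(u) {
          sigs[[u]][sample.int(signature_vocab_size, 1L)]
        }, character(1))
      }
      list(labels = labs,
           title = paste(words[seq_len(min(10L, words_per_doc))],
                         collapse = " "),
           abstract = paste(words[-seq_len(min(10L, words_per_doc))],
                            collapse = " "))
    })
    corpus_frame(
      doc_id = sprintf("%d", id_offset + seq_len(n_docs) - 1L),
      title = vapply(docs, `[[`, character(1), "title"),
      abstract = vapply(docs, `[[`, character(1), "abstract"),
      labels = lapply(docs, `[[`, "labels"),
      journal = rep("synthetic journal", n_docs),
      year = rep(2016L, n_docs)
    )
  })
}
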