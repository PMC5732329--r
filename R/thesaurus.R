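# MeSH-style thesaurus: descriptors located in a forest by dot-separated
# tree numbers. The proper-prefix relation on tree-number components defines
# ancestry; one descriptor may sit in several branches at once.

TREE_NUMBER_RE <- "^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$"

code_components <- function(codes) strsplit(codes, ".", fixed = TRUE)

#' Depth of tree-number codes
#'
#' The depth of a tree number is its number of dot-separated components;
#' depth-1 codes (e.g. `"C04"`) are roots of the forest.
#'
#' @param codes character vector of tree-number codes.
#' @return integer vector of depths.
#' @export
code_depth <- function(codes) {
  lengths(code_components(codes))
}

# All proper prefixes of one code, shortest first ("C04.557.386" ->
# c("C04", "C04.557")).
code_prefixes <- function(code) {
  parts <- code_components(code)[[1]]
  n <- length(parts)
  if (n <= 1L) return(character())
  vapply(seq_len(n - 1L), function(i) paste(parts[seq_len(i)], collapse = "."),
         character(1))
}

# Is `p` a proper component-level prefix of `codes`? Vectorised over codes.
is_proper_prefix <- function(p, codes) {
  startsWith(codes, paste0(p, "."))
}

#' Construct a thesaurus from a descriptor table
#'
#' Builds and validates a `mesh_thesaurus`: each descriptor has a unique id
#' (`ui`), a unique heading name, and one or more tree numbers; each tree
#' number is owned by exactly one descriptor.
#'
#' @param df data frame with columns `ui`, `name`, and `tree_numbers`
#'   (either a list column of character vectors or a character column of
#'   `";"`-separated codes).
#' @param allow_no_tree keep descriptors without tree numbers as isolated
#'   nodes (with a warning) instead of rejecting them. MeSH check-tags are
#'   the real-world case.
#' @return an object of class `mesh_thesaurus`.
#' @seealso [read_thesaurus()], [ancestors()], [lowest_common_ancestor()]
#' @export
as_thesaurus <- function(df, allow_no_tree = FALSE) {
  stopifnot(is.data.frame(df), all(c("ui", "name", "tree_numbers") %in% names(df)))
  ui <- as.character(df$ui)
  name <- as.character(df$name)
  tns <- df$tree_numbers
  if (!is.list(tns)) {
    tns <- lapply(as.character(tns), function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  tns <- lapply(tns, function(x) as.character(x[nzchar(x)]))

  if (anyDuplicated(ui)) {
    stop("integrity error: duplicate descriptor ui: ",
         paste(unique(ui[duplicated(ui)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("integrity error: duplicate descriptor name: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(ui)) {
    bad <- tns[[i]][!grepl(TREE_NUMBER_RE, tns[[i]])]
    if (length(bad)) {
      stop("parse error in row ", i, " (ui ", ui[i], "): malformed tree number ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(tns[[i]])) {
      stop("parse error in row ", i, " (ui ", ui[i], "): repeated tree number",
           call. = FALSE)
    }
  }
  empty <- lengths(tns) == 0L
  if (any(empty)) {
    if (!allow_no_tree) {
      stop("integrity error: descriptor(s) without tree numbers: ",
           paste(ui[empty], collapse = ", "),
           " (set allow_no_tree = TRUE to keep them as isolated nodes)",
           call. = FALSE)
    }
    warning("keeping ", sum(empty), " descriptor(s) without tree numbers as ",
            "isolated nodes", call. = FALSE)
  }
  all_codes <- unlist(tns, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    stop("integrity error: tree number owned by more than one descriptor: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "),
         call. = FALSE)
  }
  tree_index <- character(0)
  if (length(all_codes)) {
    tree_index <- stats::setNames(rep(ui, lengths(tns)), all_codes)
  }
  names(tns) <- ui
  structure(list(
    ui = ui,
    name = stats::setNames(name, ui),
    codes = tns,
    tree_index = tree_index
  ), class = "mesh_thesaurus")
}

#' @export
print.mesh_thesaurus <- function(x, ...) {
  cat("A MeSH-style thesaurus\n")
  cat("  descriptors:  ", length(x$ui), "\n", sep = "")
  cat("  tree numbers: ", length(x$tree_index), "\n", sep = "")
  if (length(x$tree_index)) {
    d <- code_depth(names(x$tree_index))
    cat("  depth:         max ", max(d), ", mean ",
        format(round(mean(d), 2)), "\n", sep = "")
    cat("  roots:        ", sum(d == 1L), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.mesh_thesaurus <- function(x, ...) {
  paste0("<mesh_thesaurus: ", length(x$ui), " descriptors>")
}

check_ui <- function(t, ui) {
  unknown <- setdiff(ui, t$ui)
  if (length(unknown)) stop_unknown_ui(unknown)
  invisible(TRUE)
}

#' Read a thesaurus file
#'
#' Reads the package's minimal thesaurus dialect: either tab-separated lines
#' `ui<TAB>name<TAB>treeNum1;treeNum2;...` (UTF-8) or a JSON array of objects
#' with keys `ui`, `name`, `treeNumbers`. The format is detected from the
#' first non-whitespace character.
#'
#' @param path path to a `.tsv` or `.json` thesaurus file.
#' @inheritParams as_thesaurus
#' @return a `mesh_thesaurus`.
#' @export
read_thesaurus <- function(path, allow_no_tree = FALSE) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  first <- regmatches(paste(raw, collapse = ""),
                      regexpr("[^[:space:]]", paste(raw, collapse = "")))
  if (length(first) && first %in% c("[", "{")) {
    rec <- jsonlite::fromJSON(paste(raw, collapse = "\n"), simplifyVector = FALSE)
    df <- data.frame(
      ui = vapply(rec, function(r) as.character(r$ui), character(1)),
      name = vapply(rec, function(r) as.character(r$name), character(1)),
      stringsAsFactors = FALSE
    )
    df$tree_numbers <- lapply(rec, function(r) {
      as.character(unlist(r$treeNumbers))
    })
  } else {
    raw <- raw[nzchar(raw)]
    if (!length(raw)) {
      return(as_thesaurus(data.frame(ui = character(), name = character(),
                                     tree_numbers = character())))
    }
    parts <- strsplit(raw, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop("parse error: line ", bad[1], " of ", path,
           " does not have 3 tab-separated fields", call. = FALSE)
    }
    df <- data.frame(
      ui = vapply(parts, `[[`, character(1), 1L),
      name = vapply(parts, `[[`, character(1), 2L),
      tree_numbers = vapply(parts, `[[`, character(1), 3L),
      stringsAsFactors = FALSE
    )
  }
  as_thesaurus(df, allow_no_tree = allow_no_tree)
}

#' Write a thesaurus file
#'
#' Serialises in the same dialects [read_thesaurus()] accepts. Descriptor and
#' tree-number order is preserved, so read/write round-trips are
#' byte-identical.
#'
#' @param t a `mesh_thesaurus`.
#' @param path output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(t, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(t, "mesh_thesaurus"))
  atomic_write(path, function(p) {
    if (format == "tsv") {
      lines <- vapply(t$ui, function(u) {
        paste(u, unname(t$name[u]), paste(t$codes[[u]], collapse = ";"),
              sep = "\t")
      }, character(1))
      writeLines(lines, p, useBytes = TRUE)
    } else {
      rec <- lapply(t$ui, function(u) {
        list(ui = u, name = unname(t$name[u]), treeNumbers = as.list(t$codes[[u]]))
      })
      jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA)
    }
  })
}

#' Ancestors of a descriptor
#'
#' A descriptor `a` is a (proper) ancestor of `ui` when some tree number of
#' `a` is a proper component-level prefix of some tree number of `ui` — the
#' transitive closure of the parent relation across every branch the
#' descriptor occupies.
#'
#' @param t a `mesh_thesaurus`.
#' @param ui descriptor id.
#' @param include_self also include `ui` itself.
#' @return character vector of descriptor uis (unordered set).
#' @export
ancestors <- function(t, ui, include_self = FALSE) {
  stopifnot(inherits(t, "mesh_thesaurus"), length(ui) == 1L)
  check_ui(t, ui)
  prefs <- unique(unlist(lapply(t$codes[[ui]], code_prefixes), use.names = FALSE))
  owners <- unique(unname(t$tree_index[prefs]))
  owners <- owners[!is.na(owners)]
  owners <- setdiff(owners, ui)
  if (include_self) owners <- union(owners, ui)
  owners
}

#' Descendants of a descriptor
#'
#' Inverse of [ancestors()]: every descriptor owning a tree number that
#' properly extends some tree number of `ui`. Never contains `ui`.
#'
#' @inheritParams ancestors
#' @return character vector of descriptor uis.
#' @export
descendants <- function(t, ui) {
  stopifnot(inherits(t, "mesh_thesaurus"), length(ui) == 1L)
  check_ui(t, ui)
  all_codes <- names(t$tree_index)
  hit <- logical(length(all_codes))
  for (code in t$codes[[ui]]) {
    hit <- hit | is_proper_prefix(code, all_codes)
  }
  setdiff(unique(unname(t$tree_index[hit])), ui)
}

# Self-inclusive witness codes: existing tree numbers that are a
# component-level prefix of (or equal to) some tree number of `ui`.
witness_codes <- function(t, ui) {
  codes <- t$codes[[ui]]
  cand <- unique(c(codes, unlist(lapply(codes, code_prefixes), use.names = FALSE)))
  cand[cand %in% names(t$tree_index)]
}

#' Lowest common ancestor of a set of descriptors
#'
#' Returns the descriptor owning the deepest tree-number code that is a
#' prefix of (or equal to) a tree number of every input descriptor, so
#' `lowest_common_ancestor(t, c(u, descendant_of_u))` is `u` itself. Ties in
#' depth are broken by the lexicographically smallest witnessing code;
#' `NA_character_` when the descriptors share no branch.
#'
#' @param t a `mesh_thesaurus`.
#' @param uis character vector of two or more descriptor ids.
#' @return a descriptor ui, or `NA_character_`.
#' @export
lowest_common_ancestor <- function(t, uis) {
  stopifnot(inherits(t, "mesh_thesaurus"))
  uis <- unique(as.character(uis))
  if (length(uis) < 2L) stop("need at least 2 distinct descriptor ids", call. = FALSE)
  check_ui(t, uis)
  common <- Reduce(intersect, lapply(uis, function(u) witness_codes(t, u)))
  if (!length(common)) return(NA_character_)
  d <- code_depth(common)
  best <- common[d == max(d)]
  best <- sort(best)[1]
  unname(t$tree_index[best])
}

# Undirected descriptor graph: one vertex per descriptor, one edge per
# existing parent/child tree-number pair.
thesaurus_graph <- function(t) {
  codes <- names(t$tree_index)
  deep <- codes[code_depth(codes) > 1L]
  parent <- vapply(deep, function(c) {
    parts <- code_components(c)[[1]]
    paste(parts[-length(parts)], collapse = ".")
  }, character(1))
  keep <- parent %in% codes
  from <- unname(t$tree_index[parent[keep]])
  to <- unname(t$tree_index[deep[keep]])
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(t$ui), name = t$ui)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    g <- igraph::simplify(g)
  }
  g
}

#' Shortest hierarchy path between two descriptors
#'
#' Minimum number of parent/child edges connecting the descriptors through
#' the tree-number forest; 0 for a descriptor and itself, `Inf` when the two
#' lie in disconnected components.
#'
#' @param t a `mesh_thesaurus`.
#' @param ui1,ui2 descriptor ids.
#' @return non-negative number, possibly `Inf`.
#' @export
shortest_path_length <- function(t, ui1, ui2) {
  stopifnot(inherits(t, "mesh_thesaurus"))
  check_ui(t, c(ui1, ui2))
  if (ui1 == ui2) return(0)
  g <- thesaurus_graph(t)
  as.numeric(igraph::distances(g, v = ui1, to = ui2))
}

#' Depth of a descriptor
#'
#' Maximum depth over the descriptor's tree numbers.
#'
#' @inheritParams ancestors
#' @return integer depth (0 for an isolated descriptor without tree numbers).
#' @export
descriptor_depth <- function(t, ui) {
  stopifnot(inherits(t, "mesh_thesaurus"), length(ui) == 1L)
  check_ui(t, ui)
  if (!length(t$codes[[ui]])) return(0L)
  max(code_depth(t$codes[[ui]]))
}

#' Ancestor report as JSON
#'
#' Exports the proper-ancestor listing of a descriptor (ui, heading name and
#' tree numbers of each ancestor) as a JSON string, the shape a graph-database
#' ancestor query would print.
#'
#' @inheritParams ancestors
#' @return a JSON string.
#' @export
ancestor_report <- function(t, ui) {
  anc <- sort(ancestors(t, ui))
  obj <- list(
    ui = ui,
    name = unname(t$name[ui]),
    ancestors = lapply(anc, function(a) {
      list(ui = a, name = unname(t$name[a]), treeNumbers = as.list(t$codes[[a]]))
    })
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
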