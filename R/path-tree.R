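#' Build a path-tree over the isomorph labels of same-size query motifs
#'
#' The path-tree is a trie over canonical-label entry tuples of every
#' isomorph of every query motif of a given size `k`. Level `i` of the trie
#' corresponds to the addition of node `i` and its children are keyed by the
#' `2i - 1` adjacency entries that node reveals (its self-loop, then its row
#' and column against the earlier nodes, in [entry_order()]). A root-to-leaf
#' path therefore spells out a complete `k^2`-entry canonical label, and each
#' leaf carries the ids of the motifs with that isomorph. During search the
#' trie answers, in one lookup per added node, whether a partial induced
#' subgraph can still extend to any query motif.
#'
#' @param motifs a motif-library tibble or list of [motif()]s, all of size `k`
#' @param k the motif size (inferred when omitted); `k <= 6`
#' @return an object of class `path_tree` with fields `k`, `root` and
#'   `motif_ids`
#' @examples
#' tr <- build_path_tree(builtin_motifs("adaptation"))
#' tr
#' @export
build_path_tree <- function(motifs, k = NULL) {
  motifs <- as_motif_list(motifs)
  if (length(motifs) == 0) rlang::abort("no motifs given")
  sizes <- vapply(motifs, motif_size, integer(1))
  if (is.null(k)) k <- sizes[1]
  k <- as.integer(k)
  if (k < 1L || k > MAX_MOTIF_SIZE) {
    rlang::abort(sprintf("motif size must be in 1..%d", MAX_MOTIF_SIZE))
  }
  if (!all(sizes == k)) {
    rlang::abort("all motifs in one path-tree must have the same node count")
  }
  root <- new_tree_node(0L)
  for (m in motifs) {
    for (lab in all_isomorph_labels(m$graph)) {
      pos <- root
      off <- 0L
      for (i in seq_len(k)) {
        len <- 2L * i - 1L
        tuple <- lab[(off + 1L):(off + len)]
        off <- off + len
        key <- label_key(tuple)
        child <- pos$children[[key]]
        if (is.null(child)) {
          child <- new_tree_node(i)
          assign(key, child, envir = pos$children)
        }
        pos <- child
      }
      pos$motifs <- sort(unique(c(pos$motifs, m$id)))
    }
  }
  structure(list(k = k, root = root,
                 motif_ids = vapply(motifs, `[[`, character(1), "id")),
            class = "path_tree")
}

new_tree_node <- function(depth) {
  node <- new.env(parent = emptyenv())
  node$depth <- depth
  node$children <- new.env(parent = emptyenv())
  node$motifs <- character()
  node
}

#' @export
print.path_tree <- function(x, ...) {
  lv <- path_tree_leaves(x)
  cat(sprintf("<path_tree> k=%d, %d motif(s), %d isomorph leaves\n",
              x$k, length(unique(x$motif_ids)), length(lv)))
  invisible(x)
}

#' Root position of a path-tree
#' @param tree a [build_path_tree()] result
#' @return the root position, depth 0
#' @export
path_tree_root <- function(tree) tree$root

#' Advance one level in a path-tree
#'
#' Given the current position at depth `i - 1`, looks up the child keyed by
#' the `2i - 1` adjacency entries revealed by the search's i-th node.
#' Returns the child position, or `NULL` ("dead end") when no query-motif
#' isomorph is compatible with the partial subgraph — the caller backtracks.
#'
#' @param position a trie position ([path_tree_root()] or a previous step)
#' @param entries integer vector over \{0, +1, -1\} of length
#'   `2 * depth - 1` for the level being entered
#' @return the next position, or `NULL` on dead end. At depth `k` the
#'   position's `motifs` field lists the matched motif ids.
#' @export
path_tree_step <- function(position, entries) {
  expected <- 2L * (position$depth + 1L) - 1L
  if (length(entries) != expected) {
    rlang::abort(sprintf("expected %d entries at depth %d, got %d",
                         expected, position$depth + 1L, length(entries)))
  }
  position$children[[label_key(as.integer(entries))]]
}

#' Motif ids at a leaf position
#' @param position a path-tree position at full depth
#' @return character vector of motif ids (empty for internal positions)
#' @export
path_tree_motifs <- function(position) position$motifs

# All root-to-leaf label sequences; each element is a list of per-level
# tuples plus the motif ids at the leaf. Children are visited in sorted key
# order, so the dump is deterministic.
path_tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node, prefix) {
    keys <- sort(ls(node$children))
    if (length(keys) == 0) {
      out[[length(out) + 1L]] <<- list(label = prefix, motifs = node$motifs)
      return(invisible())
    }
    for (key in keys) {
      child <- node$children[[key]]
      walk(child, c(prefix, as.integer(strsplit(key, " ")[[1]])))
    }
  }
  walk(tree$root, integer(0))
  out
}

# Count of trie nodes excluding the root (prefix sharing makes this at most
# the sum of leaf path lengths in levels).
path_tree_n_nodes <- function(tree) {
  count <- 0L
  walk <- function(node) {
    for (key in ls(node$children)) {
      count <<- count + 1L
      walk(node$children[[key]])
    }
  }
  walk(tree$root)
  count
}

#' Serialize a path-tree to a nested list (JSON-ready)
#'
#' Debugging aid: nested representation with children under their tuple
#' keys and motif ids at the leaves, suitable for `jsonlite::toJSON()`.
#'
#' @param x a `path_tree`
#' @param ... unused
#' @return a nested list
#' @export
as.list.path_tree <- function(x, ...) {
  dump_node <- function(node) {
    keys <- sort(ls(node$children))
    if (length(keys) == 0) return(list(motifs = node$motifs))
    stats::setNames(lapply(keys, function(k) dump_node(node$children[[k]])), keys)
  }
  list(k = x$k, tree = dump_node(x$root))
}
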