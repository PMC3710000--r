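#' Signed directed graphs
#'
#' A `signed_digraph` is the package's universal network representation: a set
#' of named nodes plus directed edges carrying a regulatory sign, `+1`
#' (activation) or `-1` (inhibition). Self-loops are permitted and carry a
#' sign. After validation at most one edge exists per ordered
#' (source, target) pair, so the graph is equivalently a matrix over
#' \{0, +1, -1\}.
#'
#' @param edges a data frame with columns `from`, `to` and `sign` (or the
#'   edge-list columns `regulator`, `relation`, `target`, where `relation` is
#'   `"+"` or `"-"`). May be `NULL` for an edgeless graph.
#' @param nodes optional character vector of node identifiers; nodes incident
#'   to an edge are always included. Use this to carry isolated nodes.
#' @param on_conflict what to do when an ordered node pair appears with both
#'   signs: `"drop"` (default) removes every edge on that pair, mirroring the
#'   exclusion of inconsistent interactions when signaling databases are
#'   integrated; `"error"` aborts instead, for strict pipelines.
#'
#' @return an object of class `signed_digraph` with fields `nodes` (sorted
#'   character vector) and `edges` (a tibble `from`, `to`, `sign`, sorted by
#'   source then target).
#' @examples
#' g <- signed_digraph(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                sign = c(1, -1)))
#' g
#' @export
signed_digraph <- function(edges = NULL, nodes = NULL,
                           on_conflict = c("drop", "error")) {
  on_conflict <- match.arg(on_conflict)
  if (is.null(edges) || nrow(edges) == 0) {
    ed <- tibble::tibble(from = character(), to = character(), sign = integer())
  } else {
    edges <- as.data.frame(edges)
    if (all(c("regulator", "relation", "target") %in% names(edges))) {
      edges <- data.frame(from = edges$regulator, to = edges$target,
                          sign = ifelse(edges$relation %in% c("-", "−"), -1L, 1L))
    }
    if (!all(c("from", "to", "sign") %in% names(edges))) {
      rlang::abort("`edges` needs columns from/to/sign (or regulator/relation/target)")
    }
    sg <- as.integer(edges$sign)
    if (any(is.na(sg)) || !all(sg %in% c(-1L, 1L))) {
      rlang::abort("edge signs must be +1 or -1")
    }
    ed <- tibble::tibble(from = as.character(edges$from),
                         to = as.character(edges$to), sign = sg)
    if (any(ed$from == "") || any(ed$to == "")) {
      rlang::abort("node identifiers must be non-empty strings")
    }
    ed <- dplyr::distinct(ed)
    # endpoints stay in the node set even when their edges are dropped below
    nodes <- c(nodes, ed$from, ed$to)
    pair <- paste(ed$from, ed$to, sep = "\r")
    conflicted <- unique(pair[duplicated(pair)])
    if (length(conflicted) > 0) {
      if (on_conflict == "error") {
        rlang::abort(paste0("conflicting signs for pair(s): ",
                            paste(gsub("\r", " -> ", conflicted), collapse = ", ")))
      }
      ed <- ed[!(pair %in% conflicted), , drop = FALSE]
    }
    ed <- dplyr::arrange(ed, .data$from, .data$to)
  }
  all_nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes %||% character()))))
  structure(list(nodes = all_nodes, edges = ed), class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  neg <- sum(x$edges$sign == -1L)
  cat(sprintf("<signed_digraph> %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(x$nodes), nrow(x$edges), nrow(x$edges) - neg, neg))
  if (nrow(x$edges) > 0) print(x$edges, n = 6)
  invisible(x)
}

#' @export
as_tibble.signed_digraph <- function(x, ...) x$edges

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

is_signed_digraph <- function(x) inherits(x, "signed_digraph")

#' Induced adjacency matrix of a node subset
#'
#' Returns the signed adjacency matrix of the subgraph induced by
#' `node_list`, in the given node order: entry `[i, j]` is the sign of the
#' edge `node_list[i] -> node_list[j]`, `0` when absent; the diagonal holds
#' self-loop signs. Induced semantics (including the zeros) is what motif
#' matching is defined over.
#'
#' @param g a [signed_digraph()]
#' @param node_list character vector of distinct node ids, all present in `g`
#' @return an integer matrix over \{0, +1, -1\} with `node_list` dimnames
#' @examples
#' g <- signed_digraph(data.frame(from = "A", to = "B", sign = 1))
#' induced_adjacency(g, c("B", "A"))
#' @export
induced_adjacency <- function(g, node_list) {
  node_list <- as.character(node_list)
  if (anyDuplicated(node_list)) rlang::abort("`node_list` has duplicates")
  missing <- setdiff(node_list, g$nodes)
  if (length(missing) > 0) {
    rlang::abort(paste0("unknown node(s): ", paste(missing, collapse = ", ")))
  }
  k <- length(node_list)
  M <- matrix(0L, k, k, dimnames = list(node_list, node_list))
  keep <- g$edges$from %in% node_list & g$edges$to %in% node_list
  e <- g$edges[keep, , drop = FALSE]
  if (nrow(e) > 0) {
    M[cbind(match(e$from, node_list), match(e$to, node_list))] <- e$sign
  }
  M
}

#' Per-node degrees and structural roles
#'
#' Computes in-degree, out-degree and total degree for every node, plus a
#' structural `role`: `"source"` (only outgoing edges), `"sink"` (only
#' incoming), `"internal"` (both), or `"isolated"`. Self-loops count toward
#' both in- and out-degree. Note that naming conventions for boundary nodes
#' differ between tools: some signaling-network viewers label sink nodes
#' (only inward edges) "input" and source nodes "output"; the neutral
#' source/sink vocabulary is used here to avoid that ambiguity.
#'
#' @param g a [signed_digraph()]
#' @return a tibble with columns `node`, `in_degree`, `out_degree`, `degree`,
#'   `role`, one row per node in sorted id order
#' @export
degree_profile <- function(g) {
  ind <- table(factor(g$edges$to, levels = g$nodes))
  outd <- table(factor(g$edges$from, levels = g$nodes))
  tibble::tibble(
    node = g$nodes,
    in_degree = as.integer(ind),
    out_degree = as.integer(outd),
    degree = .data$in_degree + .data$out_degree,
    role = dplyr::case_when(
      .data$degree == 0L ~ "isolated",
      .data$in_degree == 0L ~ "source",
      .data$out_degree == 0L ~ "sink",
      TRUE ~ "internal"
    )
  )
}

#' Convert to an igraph object
#'
#' Builds an [igraph::graph_from_data_frame()] representation with the edge
#' sign stored in the `sign` edge attribute, for layout and path queries.
#'
#' @param g a [signed_digraph()]
#' @return an igraph graph
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}
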