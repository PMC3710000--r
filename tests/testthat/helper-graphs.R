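# Small builders used across tests.

chain_graph <- function(nodes, signs = rep(1L, length(nodes) - 1)) {
  signed_digraph(data.frame(from = nodes[-length(nodes)], to = nodes[-1],
                            sign = signs))
}

cycle_graph <- function(nodes, signs = rep(1L, length(nodes))) {
  signed_digraph(data.frame(from = nodes, to = c(nodes[-1], nodes[1]),
                            sign = signs))
}

# Independent signed-isomorphism check via igraph VF2 (edge-colored).
# igraph's VF2 rejects loop edges, so callers must pass loop-free graphs.
vf2_isomorphic <- function(a, b) {
  if (length(a$nodes) != length(b$nodes) || nrow(a$edges) != nrow(b$edges)) {
    return(FALSE)
  }
  ga <- as_igraph(a); gb <- as_igraph(b)
  igraph::isomorphic(ga, gb, method = "vf2",
                     edge.color1 = ifelse(igraph::E(ga)$sign > 0, 1L, 2L),
                     edge.color2 = ifelse(igraph::E(gb)$sign > 0, 1L, 2L))
}

# Random small signed digraph (possibly with self-loops) for property tests.
random_small_graph <- function(k, p_edge = 0.5, p_neg = 0.3, loops = FALSE) {
  ids <- LETTERS[seq_len(k)]
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  if (!loops) pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) return(signed_digraph(NULL, nodes = ids))
  e <- pairs[keep, ]
  e$sign <- ifelse(stats::runif(nrow(e)) < p_neg, -1L, 1L)
  signed_digraph(e, nodes = ids)
}

node_set_key <- function(nodes) paste(sort(nodes), collapse = "|")

sorted_set_list <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}
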