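#' Sign composition along a regulatory cascade
#'
#' The total regulatory effect of a cascade is the product of its edge
#' signs: an even number of inhibitions yields net activation, an odd
#' number net inhibition.
#'
#' @param signs vector over \{+1, -1\}, one per traversed edge
#' @return `+1` or `-1`
#' @examples
#' sign_product(c(1, -1, 1))
#' @export
sign_product <- function(signs) {
  signs <- as.integer(signs)
  if (length(signs) == 0) rlang::abort("`signs` must be non-empty")
  if (!all(signs %in% c(-1L, 1L))) rlang::abort("signs must be +1 or -1")
  as.integer(prod(signs))
}

#' Compress a signaling network by node-based reduction
#'
#' Iteratively eliminates intermediate nodes, replacing each with bypass
#' edges whose signs are the products along the removed two-edge segments,
#' so the reduced network preserves the sign dynamics of the original. A
#' node `v` is eliminable when all of the following hold: it is not
#' protected; it has no self-loop; it has at least one predecessor and one
#' successor; it lies on a linear segment (`in_degree == 1` or
#' `out_degree == 1`, the unit-degree gate); and every bypass edge
#' `(p, s, sign(p,v) * sign(v,s))` is sign-compatible with existing and
#' co-created edges on `(p, s)` (a conflict aborts that node's elimination
#' entirely — dropping edges would destroy dynamics information). Nodes are
#' scanned in sorted-id order, repeatedly, until a full pass eliminates
#' nothing; the result is a fixpoint and deterministic.
#'
#' Collapsing a 2-cycle through an eliminated node creates a self-loop on
#' the surviving node; this is permitted by default because compressed motif
#' forms include self-regulation, and path expansion later restores the true
#' loop length.
#'
#' @param g a validated [signed_digraph()]
#' @param protected node ids never eliminated (e.g. the source/target pair
#'   of a path-constrained analysis)
#' @param unit_degree_gate require `in_degree == 1 || out_degree == 1`
#'   (default `TRUE`): restricts elimination to linear-cascade nodes and
#'   bounds bypass-edge growth
#' @param allow_new_self_loops permit bypass self-loops from collapsing
#'   2-cycles (default `TRUE`)
#' @return an object of class `compressed_network`: list with `reduced`
#'   (the compressed [signed_digraph()]), `eliminated` (character),
#'   `original`, `protected`
#' @examples
#' g <- read_network(c("A + B", "B - C", "C + D"))
#' compress_network(g, protected = c("A", "D"))
#' @export
compress_network <- function(g, protected = character(),
                             unit_degree_gate = TRUE,
                             allow_new_self_loops = TRUE) {
  stopifnot(is_signed_digraph(g))
  protected <- as.character(protected)
  missing <- setdiff(protected, g$nodes)
  if (length(missing) > 0) {
    rlang::abort(paste0("protected node(s) not in network: ",
                        paste(missing, collapse = ", ")))
  }
  ids <- g$nodes
  n <- length(ids)
  A <- induced_adjacency(g, ids)
  alive <- rep(TRUE, n)
  prot <- ids %in% protected

  repeat {
    eliminated_this_pass <- FALSE
    for (v in seq_len(n)) {
      if (!alive[v] || prot[v] || A[v, v] != 0L) next
      preds <- which(A[, v] != 0L & alive); preds <- preds[preds != v]
      succs <- which(A[v, ] != 0L & alive); succs <- succs[succs != v]
      indeg <- length(preds); outdeg <- length(succs)
      if (indeg < 1L || outdeg < 1L) next
      if (unit_degree_gate && indeg != 1L && outdeg != 1L) next
      # propose bypasses; abort elimination on any sign conflict
      ok <- TRUE
      bp <- matrix(0L, 0L, 3L)
      for (p in preds) for (s in succs) {
        sigma <- A[p, v] * A[v, s]
        if (p == s && !allow_new_self_loops && A[p, s] == 0L) { ok <- FALSE; break }
        if (A[p, s] != 0L && A[p, s] != sigma) { ok <- FALSE; break }
        bp <- rbind(bp, c(p, s, sigma))
      }
      if (!ok) next
      A[v, ] <- 0L; A[, v] <- 0L
      alive[v] <- FALSE
      for (j in seq_len(nrow(bp))) A[bp[j, 1], bp[j, 2]] <- bp[j, 3]
      eliminated_this_pass <- TRUE
    }
    if (!eliminated_this_pass) break
  }

  keep <- which(alive)
  nz <- which(A != 0L, arr.ind = TRUE)
  reduced <- signed_digraph(
    if (nrow(nz) > 0) {
      data.frame(from = ids[nz[, 1]], to = ids[nz[, 2]], sign = A[nz])
    } else NULL,
    nodes = ids[keep]
  )
  structure(list(reduced = reduced, eliminated = ids[!alive],
                 original = g, protected = protected),
            class = "compressed_network")
}

#' @export
print.compressed_network <- function(x, ...) {
  cat(sprintf("<compressed_network> %d -> %d nodes, %d -> %d edges (%d eliminated)\n",
              n_nodes(x$original), n_nodes(x$reduced),
              n_edges(x$original), n_edges(x$reduced), length(x$eliminated)))
  invisible(x)
}

#' @describeIn compress_network tidy method: the reduced network's edge list
#'   with a per-node `eliminated` flag available via `glance()`
#' @param x a `compressed_network`
#' @param ... unused
#' @export
tidy.compressed_network <- function(x, ...) x$reduced$edges

#' @describeIn compress_network glance method: one-row compression summary
#' @export
glance.compressed_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = n_nodes(x$original),
    n_nodes_reduced = n_nodes(x$reduced),
    n_edges = n_edges(x$original),
    n_edges_reduced = n_edges(x$reduced),
    n_eliminated = length(x$eliminated),
    node_reduction = 1 - n_nodes(x$reduced) / max(1L, n_nodes(x$original))
  )
}
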