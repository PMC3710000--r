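#' Enumerate connected k-node subgraphs (ESU)
#'
#' Yields every weakly connected k-node subset of `g` exactly once, as the
#' ordered node list in which the enumeration added its members. Nodes are
#' given integer enumeration labels in sorted-id order; a subgraph is grown
#' from its lowest-labelled node (the root) and may only be extended by
#' exclusive neighbours carrying a label greater than the root's — the
#' classic ESU scheme, which guarantees each connected set is generated
#' once, from a single discovery order. Connectivity is over the underlying
#' undirected graph (in- plus out-neighbours); self-loops never connect a
#' node to anything new and are ignored here (they still appear in induced
#' adjacency diagonals).
#'
#' @param g a [signed_digraph()]
#' @param k subgraph size, `k >= 1`
#' @return a list of character node vectors in discovery order, with
#'   attribute `"visits"` counting visited partial subgraphs
#' @examples
#' g <- read_network(c("a + b", "b + c"))
#' enumerate_connected_subgraphs(g, 2)
#' @export
enumerate_connected_subgraphs <- function(g, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) rlang::abort("`k` must be a positive integer")
  idx <- graph_index(g)
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 256L); acc$n <- 0L; acc$visits <- 0L
  esu_run(idx, k, acc, emit = function(vs) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$out)) acc$out <- c(acc$out, vector("list", length(acc$out)))
    acc$out[[acc$n]] <- idx$ids[vs]
  })
  structure(acc$out[seq_len(acc$n)], visits = acc$visits)
}

# Core ESU recursion. `step_fun(vs, w)` is called before adding node w to
# the partial subgraph vs; returning FALSE prunes that extension (path-tree
# feasibility). `emit(vs)` receives every accepted k-node discovery order.
esu_run <- function(idx, k, acc, emit, step_fun = NULL) {
  n <- idx$n
  und <- idx$und_nbrs
  extend <- function(root, vs, ext, blocked) {
    acc$visits <- acc$visits + 1L
    if (length(vs) == k) { emit(vs); return(invisible()) }
    while (length(ext) > 0) {
      w <- ext[1L]; ext <- ext[-1L]
      if (!is.null(step_fun) && !step_fun(vs, w)) next
      nb <- und[[w]]
      vex <- nb[nb > root & !blocked[nb]]
      blocked2 <- blocked
      blocked2[vex] <- TRUE
      extend(root, c(vs, w), c(ext, vex), blocked2)
      if (!is.null(step_fun)) step_fun(NULL, w)  # signal backtrack
    }
  }
  for (v in seq_len(n)) {
    if (k == 1L) {
      if (is.null(step_fun) || step_fun(integer(0), v)) {
        acc$visits <- acc$visits + 1L
        emit(v)
        if (!is.null(step_fun)) step_fun(NULL, v)
      }
      next
    }
    nb <- und[[v]]
    ext <- nb[nb > v]
    blocked <- rep(FALSE, n)
    blocked[v] <- TRUE
    blocked[nb] <- TRUE
    if (!is.null(step_fun)) {
      if (!step_fun(integer(0), v)) next
      extend(v, v, ext, blocked)
      step_fun(NULL, v)
    } else {
      extend(v, v, ext, blocked)
    }
  }
  invisible()
}

#' Find all induced matches of path-tree query motifs
#'
#' Runs the ESU enumeration over `g` and, as each node is added to a
#' partial subgraph, feeds the `2i - 1` newly revealed induced-adjacency
#' entries (the node's self-loop, then its row and column against the
#' earlier nodes) to the path-tree. A dead end prunes the entire branch;
#' reaching a leaf at depth `k` emits one match per motif id stored there.
#' Matching is induced (exact-zero) semantics: the full signed adjacency of
#' the k nodes, absences included, must be an isomorph of the query motif.
#'
#' @param g a [signed_digraph()]
#' @param tree a [build_path_tree()] over the query motifs
#' @param prune feed the trie during growth (default). With
#'   `prune = FALSE` the full enumeration runs and labels are checked only
#'   at depth `k`; results are identical, used to measure pruning
#'   effectiveness
#' @return a tibble with columns `motif_id`, `nodes` (list of character
#'   vectors in discovery order) and `matrix` (list of induced adjacency
#'   matrices under that order), plus attribute `"visits"` (number of
#'   partial subgraphs visited)
#' @examples
#' g <- read_network(c("A + B", "B - A"))
#' tr <- build_path_tree(builtin_motifs("oscillation")[1:2, ])
#' find_matches(g, tr)
#' @export
find_matches <- function(g, tree, prune = TRUE) {
  stopifnot(inherits(tree, "path_tree"))
  k <- tree$k
  idx <- graph_index(g)
  A <- idx$A
  acc <- new.env(parent = emptyenv())
  acc$visits <- 0L
  acc$motif <- character(0)
  acc$nodes <- list()
  acc$mats <- list()

  emit_leaf <- function(vs, leaf) {
    ids <- leaf$motifs
    if (length(ids) == 0) return(invisible())
    node_names <- idx$ids[vs]
    M <- A[vs, vs, drop = FALSE]
    dimnames(M) <- list(node_names, node_names)
    for (id in ids) {
      acc$motif <- c(acc$motif, id)
      acc$nodes[[length(acc$nodes) + 1L]] <- node_names
      acc$mats[[length(acc$mats) + 1L]] <- M
    }
  }

  if (prune) {
    # trie position stack mirrors the recursion depth
    stack <- vector("list", k + 1L)
    stack[[1L]] <- tree$root
    depth <- 0L
    step_fun <- function(vs, w) {
      if (is.null(vs)) { depth <<- depth - 1L; return(TRUE) }  # backtrack
      entries <- c(A[w, w], A[w, vs], A[vs, w])
      nxt <- stack[[depth + 1L]]$children[[label_key(entries)]]
      if (is.null(nxt)) return(FALSE)
      depth <<- depth + 1L
      stack[[depth + 1L]] <<- nxt
      TRUE
    }
    esu_run(idx, k, acc, emit = function(vs) emit_leaf(vs, stack[[k + 1L]]),
            step_fun = step_fun)
  } else {
    eo <- entry_order(k)
    esu_run(idx, k, acc, emit = function(vs) {
      lab <- A[vs, vs, drop = FALSE][eo]
      pos <- tree$root
      off <- 0L
      for (i in seq_len(k)) {
        len <- 2L * i - 1L
        pos <- pos$children[[label_key(lab[(off + 1L):(off + len)])]]
        off <- off + len
        if (is.null(pos)) return(invisible())
      }
      emit_leaf(vs, pos)
    })
  }

  res <- tibble::tibble(motif_id = acc$motif, nodes = acc$nodes,
                        matrix = acc$mats)
  attr(res, "visits") <- acc$visits
  attr(res, "k") <- k
  res
}

#' Count induced matches per query motif
#'
#' Convenience aggregation of [find_matches()] across motif sizes: builds
#' one path-tree per size present in `motifs`, searches once per size, and
#' tabulates match counts per motif (one count per matched node set).
#'
#' @param g a [signed_digraph()]
#' @param motifs a motif-library tibble or list of [motif()]s
#' @return a tibble `motif_id`, `n_matches`, in library order, zeros
#'   included
#' @export
count_matches <- function(g, motifs) {
  ml <- as_motif_list(motifs)
  ids <- vapply(ml, `[[`, character(1), "id")
  sizes <- vapply(ml, motif_size, integer(1))
  counts <- stats::setNames(integer(length(ids)), ids)
  for (k in sort(unique(sizes))) {
    tr <- build_path_tree(ml[sizes == k], k)
    m <- find_matches(g, tr)
    if (nrow(m) > 0) {
      tab <- table(m$motif_id)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  tibble::tibble(motif_id = ids, n_matches = unname(counts))
}
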