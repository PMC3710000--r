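#' Recover original-network paths for a compressed edge
#'
#' A compressed edge `(a, b, sign)` stands for one or more regulatory
#' cascades of the original network. This depth-first search enumerates all
#' simple paths from `a` to `b` subject to the two recovery constraints:
#' every internal node belongs to the eliminated set, and the sign product
#' along the path equals the compressed edge's sign. The direct edge
#' `(a, b, sign)`, when present in the original network, qualifies as a
#' length-1 path. Expanding a compressed self-loop (`a == b`) permits the
#' start and end node to coincide, recovering feedback loops that
#' compression collapsed; such cycles need at least one edge (the direct
#' self-loop) or pass through eliminated nodes.
#'
#' @param original the uncompressed [signed_digraph()]
#' @param from,to endpoint node ids (equal for a self-loop)
#' @param sign the compressed edge sign, `+1` or `-1`
#' @param eliminated node ids removed by compression (allowed as internals)
#' @param max_len maximum path length in edges (default 8); bounds the DFS
#' @return a tibble with columns `path` (list of character node sequences,
#'   in lexicographic order), `sign` and `length`; zero rows when no path
#'   satisfies the constraints
#' @examples
#' g <- read_network(c("A + B", "B - C", "C + D"))
#' expand_edge(g, "A", "D", -1, eliminated = c("B", "C"))
#' @export
expand_edge <- function(original, from, to, sign, eliminated, max_len = 8L) {
  stopifnot(is_signed_digraph(original))
  sign <- as.integer(sign)
  if (!sign %in% c(-1L, 1L)) rlang::abort("`sign` must be +1 or -1")
  idx <- graph_index(original)
  a <- match(from, idx$ids); b <- match(to, idx$ids)
  if (is.na(a) || is.na(b)) rlang::abort("`from`/`to` must be nodes of `original`")
  elim <- match(intersect(eliminated, idx$ids), idx$ids)
  is_elim <- rep(FALSE, idx$n); is_elim[elim] <- TRUE
  A <- idx$A

  paths <- list(); signs <- integer(0)
  in_path <- rep(FALSE, idx$n)
  maybe_emit <- function(seq_ix, prod) {
    if (prod == sign) {
      paths[[length(paths) + 1L]] <<- idx$ids[seq_ix]
      signs <<- c(signs, prod)
    }
  }
  # len = edges traversed so far; closing via w == b adds one more edge
  dfs <- function(u, seq_ix, prod, len) {
    for (w in idx$out_nbrs[[u]]) {
      if (w == b && len + 1L <= max_len) {
        maybe_emit(c(seq_ix, b), prod * A[u, b])
      }
      if (w != b && is_elim[w] && !in_path[w] && len + 2L <= max_len) {
        in_path[w] <<- TRUE
        dfs(w, c(seq_ix, w), prod * A[u, w], len + 1L)
        in_path[w] <<- FALSE
      }
    }
  }

  if (a == b && A[a, a] != 0L && max_len >= 1L) maybe_emit(c(a, a), A[a, a])
  in_path[a] <- TRUE
  dfs(a, a, 1L, 0L)

  if (length(paths) == 0) {
    return(tibble::tibble(path = list(), sign = integer(), length = integer()))
  }
  res <- tibble::tibble(path = paths, sign = signs,
                        length = vapply(paths, length, integer(1)) - 1L)
  ord <- order(vapply(res$path, paste, character(1), collapse = "\r"))
  res <- res[ord, , drop = FALSE]
  res[!duplicated(vapply(res$path, paste, character(1), collapse = "\r")), , drop = FALSE]
}

# Edges of a match in a fixed scan order: diagonal then off-diagonal,
# row-major over the discovery-order matrix.
match_edges <- function(M) {
  nz <- which(M != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0) {
    return(tibble::tibble(from = character(), to = character(), sign = integer()))
  }
  ord <- order(nz[, 1], nz[, 2])
  nz <- nz[ord, , drop = FALSE]
  tibble::tibble(from = rownames(M)[nz[, 1]], to = colnames(M)[nz[, 2]],
                 sign = M[nz])
}

path_internals <- function(p) {
  if (length(p) <= 2) character(0) else p[2:(length(p) - 1)]
}

path_key <- function(p) paste(p, collapse = ">")

# Edge multiset of an expanded instance, as a canonical sorted key.
instance_edge_key <- function(paths) {
  edges <- unlist(lapply(paths, function(p) {
    if (length(p) < 2) return(character(0))
    paste0(p[-length(p)], ">", p[-1])
  }))
  paste(sort(edges), collapse = "|")
}

#' Instantiate full-size motif instances from compressed matches
#'
#' Turns each compressed-level match into concrete regulatory motifs of the
#' original network by choosing one recovered path per matched edge
#' (Cartesian selection over the per-edge [expand_edge()] lists). A
#' selection is kept only when the internal nodes of its paths are pairwise
#' disjoint and disjoint from the match nodes — overlapping paths would not
#' realize the motif's circuit topology (relax with
#' `allow_shared_internals = TRUE`). Motifs carrying a minimum-size
#' annotation drop instances spanning fewer distinct original nodes.
#' Instances are deduplicated by their full edge multiset, across matches.
#'
#' @param matches a [find_matches()] tibble (over the compressed network)
#' @param original the uncompressed [signed_digraph()]
#' @param eliminated node ids eliminated by compression (empty when
#'   compression was skipped)
#' @param motifs the query library (for `min_size` lookup); optional
#' @param max_len per-path length cap passed to [expand_edge()]
#' @param allow_shared_internals keep instances whose paths share internal
#'   nodes (default `FALSE`)
#' @return a tibble with one row per motif instance: `motif_id`,
#'   `match_nodes` (compressed-level node list), `nodes` (all distinct
#'   original nodes), `size`, and `edges` — a nested tibble per instance
#'   with `from`, `to`, `sign`, `length` and the rendered `path` string
#'   (`"A>B>C"`) for each motif edge
#' @export
instantiate_matches <- function(matches, original, eliminated = character(),
                                motifs = NULL, max_len = 8L,
                                allow_shared_internals = FALSE) {
  min_size <- integer(0)
  if (!is.null(motifs)) {
    ml <- as_motif_list(motifs)
    min_size <- stats::setNames(vapply(ml, `[[`, integer(1), "min_size"),
                                vapply(ml, `[[`, character(1), "id"))
  }
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(matches))) {
    mid <- matches$motif_id[r]
    M <- matches$matrix[[r]]
    medges <- match_edges(M)
    if (nrow(medges) == 0) next
    exps <- vector("list", nrow(medges))
    empty <- FALSE
    for (j in seq_len(nrow(medges))) {
      ex <- expand_edge(original, medges$from[j], medges$to[j], medges$sign[j],
                        eliminated, max_len = max_len)
      if (nrow(ex) == 0) { empty <- TRUE; break }
      exps[[j]] <- ex
    }
    if (empty) next
    grid <- expand.grid(lapply(exps, function(e) seq_len(nrow(e))),
                        KEEP.OUT.ATTRS = FALSE)
    match_nodes <- rownames(M)
    for (gidx in seq_len(nrow(grid))) {
      paths <- lapply(seq_along(exps), function(j) exps[[j]]$path[[grid[gidx, j]]])
      internals <- lapply(paths, path_internals)
      if (!allow_shared_internals) {
        all_int <- unlist(internals)
        if (anyDuplicated(all_int) || length(intersect(all_int, match_nodes)) > 0) next
      }
      nodes <- sort(unique(c(match_nodes, unlist(internals))))
      msz <- if (mid %in% names(min_size)) min_size[[mid]] else NA_integer_
      if (!is.na(msz) && length(nodes) < msz) next
      key <- paste0(mid, "#", instance_edge_key(paths))
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      inst_size <- length(nodes)
      out[[length(out) + 1L]] <- tibble::tibble(
        motif_id = mid,
        match_nodes = list(match_nodes),
        nodes = list(nodes),
        size = inst_size,
        edges = list(tibble::tibble(
          from = medges$from, to = medges$to, sign = medges$sign,
          length = vapply(paths, length, integer(1)) - 1L,
          path = vapply(paths, path_key, character(1))
        ))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(motif_id = character(), match_nodes = list(),
                          nodes = list(), size = integer(), edges = list()))
  }
  dplyr::bind_rows(out)
}

#' Per-edge structural properties of motif instances
#'
#' Flattens the nested per-edge information of [instantiate_matches()]
#' output into one row per (instance, motif edge): the realized path, its
#' sign, its length in original-network edges, and the instance's total
#' size in distinct molecules.
#'
#' @param instances an [instantiate_matches()] tibble
#' @return an unnested tibble with columns `motif_id`, `instance`, `from`,
#'   `to`, `sign`, `length`, `path`, `size`
#' @export
structural_properties <- function(instances) {
  if (nrow(instances) == 0) {
    return(tibble::tibble(motif_id = character(), instance = integer(),
                          from = character(), to = character(),
                          sign = integer(), length = integer(),
                          path = character(), size = integer()))
  }
  instances %>%
    dplyr::mutate(instance = dplyr::row_number()) %>%
    dplyr::select("motif_id", "instance", "edges", "size") %>%
    tidyr::unnest("edges") %>%
    dplyr::select("motif_id", "instance", "from", "to", "sign", "length",
                  "path", "size")
}
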