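#' Generate a random signed directed network
#'
#' Uniform fixed-edge-count model: `m` distinct ordered node pairs are
#' sampled without replacement (so no conflicting parallel edges can arise
#' by construction) and each edge is inhibitory with probability
#' `negative_fraction`. The default negative fraction of 0.18 mirrors the
#' inhibitory share observed in large integrated human signaling networks
#' (about 18% of edges). Identical arguments and seed give an identical
#' graph; the caller's RNG state is untouched.
#'
#' @param n node count; node ids are zero-padded (`"n001"`, ...) so sorted
#'   id order equals numeric order
#' @param m edge count, at most `n*(n-1)` (plus `n` with self-loops)
#' @param negative_fraction probability an edge is inhibitory
#' @param allow_self_loops include self-pairs in the sample space
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a [signed_digraph()] with exactly `n` nodes and `m` edges
#' @examples
#' random_network(10, 20, seed = 1)
#' @export
random_network <- function(n, m, negative_fraction = 0.18,
                           allow_self_loops = FALSE, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (negative_fraction < 0 || negative_fraction > 1) {
    rlang::abort("`negative_fraction` must be in [0, 1]")
  }
  max_m <- n * (n - 1L) + if (allow_self_loops) n else 0L
  if (m > max_m) {
    rlang::abort(sprintf("m = %d exceeds the %d possible ordered pairs", m, max_m))
  }
  ids <- sprintf(paste0("n%0", nchar(n), "d"), seq_len(n))
  with_seed(seed, {
    # ordered pairs encoded 0..n^2-1; remove the diagonal unless allowed
    pool <- seq_len(n * n) - 1L
    if (!allow_self_loops) pool <- pool[pool %/% n != pool %% n]
    chosen <- if (m > 0) sample(pool, m) else integer(0)
    from <- chosen %/% n + 1L
    to <- chosen %% n + 1L
    signs <- ifelse(stats::runif(m) < negative_fraction, -1L, 1L)
    signed_digraph(
      if (m > 0) data.frame(from = ids[from], to = ids[to], sign = signs) else NULL,
      nodes = ids
    )
  })
}

# Brute-force enumeration of all weakly connected k-node subsets, by subset
# filtering. Independent of the ESU machinery; cost C(n,k), so guarded.
all_connected_ksets <- function(g, k) {
  idx <- graph_index(g)
  n <- idx$n
  k <- as.integer(k)
  if (k > n) return(list())
  if (choose(n, k) > 5e5) rlang::abort("too many subsets for brute force")
  und <- idx$und_nbrs
  connected <- function(S) {
    if (length(S) == 1) return(TRUE)
    seen <- S[1]
    frontier <- S[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(intersect(unlist(und[frontier]), S), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    length(seen) == length(S)
  }
  subs <- utils::combn(n, k)
  keep <- apply(subs, 2, connected)
  lapply(which(keep), function(j) idx$ids[subs[, j]])
}

#' Sample non-isomorphic query motifs from a network
#'
#' Draws connected induced k-node subgraphs of `g`, deduplicates them by
#' canonical form, and returns up to `count` pairwise non-isomorphic
#' motifs. When the network holds fewer than `count` non-isomorphic
#' connected k-subgraphs, all of them are returned. For small networks the
#' connected subsets are enumerated exhaustively; larger networks are
#' sampled by random connected growth.
#'
#' @param g a [signed_digraph()]
#' @param k motif size, `k <= 6`
#' @param count maximum number of motifs
#' @param seed integer seed
#' @return a motif-library tibble of `custom`-class motifs with ids
#'   `"q<k>_<i>"`
#' @export
random_query_motifs <- function(g, k, count = 50L, seed = NULL) {
  k <- as.integer(k)
  if (k > MAX_MOTIF_SIZE) rlang::abort(sprintf("k must be <= %d", MAX_MOTIF_SIZE))
  idx <- graph_index(g)
  with_seed(seed, {
    sets <- if (choose(idx$n, k) <= 2e4) {
      sample(all_connected_ksets(g, k))
    } else {
      # random connected growth, generously oversampled
      tries <- 400L * count
      out <- vector("list", tries)
      for (t in seq_len(tries)) {
        v <- sample.int(idx$n, 1)
        S <- v
        while (length(S) < k) {
          nb <- setdiff(unique(unlist(idx$und_nbrs[S])), S)
          if (length(nb) == 0) break
          S <- c(S, nb[sample.int(length(nb), 1)])
        }
        if (length(S) == k) out[[t]] <- idx$ids[S]
      }
      unique(out[!vapply(out, is.null, logical(1))])
    }
    motifs <- list()
    keys <- character(0)
    for (S in sets) {
      M <- induced_adjacency(g, sort(S))
      key <- label_key(canonical_form(M))
      if (key %in% keys) next
      keys <- c(keys, key)
      motifs[[length(motifs) + 1L]] <- motif(
        sprintf("q%d_%d", k, length(motifs) + 1L),
        signed_digraph(matrix_to_edges(M), nodes = rownames(M)),
        class = "custom", note = "sampled query subgraph")
      if (length(motifs) >= count) break
    }
    library_tibble(motifs)
  })
}

matrix_to_edges <- function(M) {
  nz <- which(M != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0) return(NULL)
  data.frame(from = rownames(M)[nz[, 1]], to = colnames(M)[nz[, 2]], sign = M[nz])
}

#' Precompute induced-subgraph keys for the brute-force oracle
#'
#' For every k-subset of nodes (ascending id order) computes the row-major
#' flattening of the induced signed adjacency matrix as a string key.
#' [oracle_matches()] accepts the result to amortize the subset pass over
#' many query motifs against the same network.
#'
#' @param g a [signed_digraph()]
#' @param k subset size
#' @return a list with `keys` (character, one per subset) and `sets`
#'   (k x C(n,k) index matrix of node ids)
#' @export
oracle_subset_keys <- function(g, k) {
  idx <- graph_index(g)
  n <- idx$n
  k <- as.integer(k)
  if (n > 40L || k > 5L) {
    rlang::abort("oracle guard: needs n <= 40 and k <= 5 (C(n,k)*k! work)")
  }
  subs <- utils::combn(n, k)
  Avec <- as.vector(idx$A)
  # row-major flatten of A[S, S]: entry (i, j) read j fastest
  ii <- rep(seq_len(k), each = k)
  jj <- rep(seq_len(k), times = k)
  parts <- vector("list", k * k)
  for (e in seq_len(k * k)) {
    parts[[e]] <- Avec[(subs[jj[e], ] - 1L) * n + subs[ii[e], ]]
  }
  keys <- do.call(paste, c(parts, sep = " "))
  list(keys = keys, sets = matrix(idx$ids[subs], nrow = k), n = n)
}

#' Brute-force induced motif matching (oracle)
#'
#' The transparent definition of matching: a k-subset of nodes matches when
#' some bijection maps the motif's signed edges exactly onto the subset's
#' induced signed adjacency (absences included). Implemented as subset
#' enumeration on the network side crossed with exhaustive node
#' permutations on the motif side, with no shared code with the path-tree
#' or search modules — this is the reference every search result is tested
#' against. Cost is C(n,k) * k!, so inputs are guarded to n <= 40, k <= 5.
#'
#' @param g a [signed_digraph()]
#' @param m a [motif()] or [signed_digraph()] query
#' @param subset_keys optional precomputed [oracle_subset_keys()] for `g`
#'   and the motif's size
#' @return a list of matched node sets (sorted character vectors), in
#'   lexicographic order
#' @examples
#' g <- read_network(c("A + B", "B - A", "B + C"))
#' oracle_matches(g, builtin_motifs()$motif[[2]])
#' @export
oracle_matches <- function(g, m, subset_keys = NULL) {
  graph <- if (inherits(m, "regmotif_motif")) m$graph else m
  M <- induced_adjacency(graph, graph$nodes)
  k <- nrow(M)
  if (is.null(subset_keys)) subset_keys <- oracle_subset_keys(g, k)
  stopifnot(nrow(subset_keys$sets) == k)
  # row-major keys of every permuted motif matrix
  perms <- permutations_of(k)
  pkeys <- unique(vapply(seq_len(nrow(perms)), function(i) {
    P <- M[perms[i, ], perms[i, ], drop = FALSE]
    paste(as.vector(t(P)), collapse = " ")
  }, character(1)))
  hit <- subset_keys$keys %in% pkeys
  sets <- lapply(which(hit), function(j) sort(subset_keys$sets[, j]))
  sets[order(vapply(sets, paste, character(1), collapse = "\r"))]
}
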