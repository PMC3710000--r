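MAX_MOTIF_SIZE <- 6L

#' Canonical entry order of a k x k signed adjacency matrix
#'
#' The canonical label of a k-node signed digraph linearizes its adjacency
#' matrix in a fixed node-incremental order: for node i = 1..k, first the
#' diagonal entry (i, i), then row entries (i, 1)..(i, i-1), then column
#' entries (1, i)..(i-1, i). Node i thus contributes 2i - 1 entries and the
#' total length is k^2. For k = 3 the order is (1,1), (2,2), (2,1), (1,2),
#' (3,3), (3,1), (3,2), (1,3), (2,3). This incremental layout is what lets
#' the subgraph search check exactly the entries revealed by each newly
#' added node.
#'
#' @param k number of nodes, `k >= 1`
#' @return an integer matrix with `k^2` rows and columns `row`, `col`
#'   (1-based indices)
#' @examples
#' entry_order(3)
#' @export
entry_order <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) rlang::abort("`k` must be a positive integer")
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(k)) {
    prev <- seq_len(i - 1L)
    rows <- c(rows, i, rep(i, i - 1L), prev)
    cols <- c(cols, i, prev, rep(i, i - 1L))
  }
  cbind(row = rows, col = cols)
}

check_sign_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    rlang::abort("adjacency matrix must be square")
  }
  if (!all(m %in% c(-1L, 0L, 1L))) {
    rlang::abort("adjacency entries must be in {-1, 0, +1}")
  }
  matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Canonical label of a signed adjacency matrix
#'
#' Reads the matrix entries off in [entry_order()] and returns them as an
#' integer vector of length `k^2`. The mapping is bijective for fixed `k`.
#'
#' @param m a square matrix over \{0, +1, -1\}
#' @return integer vector of length `nrow(m)^2`
#' @examples
#' canonical_label(rbind(c(0, 1), c(-1, 0)))
#' @export
canonical_label <- function(m) {
  m <- check_sign_matrix(m)
  unname(m[entry_order(nrow(m))])
}

label_key <- function(label) paste(label, collapse = " ")

# Total order on labels: entries ranked 0 < +1 < -1 (sparse graphs sort
# first), compared lexicographically. Encoded as a sortable digit string.
label_rank_key <- function(label) {
  paste(c("1" = "1", "0" = "0", "-1" = "2")[as.character(label)], collapse = "")
}

as_motif_matrix <- function(x) {
  if (is_signed_digraph(x)) induced_adjacency(x, x$nodes)
  else check_sign_matrix(x)
}

#' All canonical labels of the isomorphs of a small signed digraph
#'
#' Enumerates every node ordering of `m` (all k! permutations), labels the
#' permuted adjacency matrix with [canonical_label()], and returns the
#' distinct labels. Their number equals `k!/|Aut(m)|` where `Aut(m)` is the
#' automorphism group. Exhaustive permutation replaces specialized canonical
#' labeling tools and is exact for motif-sized graphs (`k <= 6`).
#'
#' @param m a [signed_digraph()] or square sign matrix with at most 6 nodes
#' @return a list of integer label vectors, sorted by the canonical entry
#'   order (0 < +1 < -1)
#' @examples
#' cyc <- signed_digraph(data.frame(from = c("A", "B", "C"),
#'                                  to = c("B", "C", "A"), sign = 1))
#' length(all_isomorph_labels(cyc))  # 2 = 3!/|Aut| with |Aut| = 3
#' @export
all_isomorph_labels <- function(m) {
  M <- as_motif_matrix(m)
  k <- nrow(M)
  if (k > MAX_MOTIF_SIZE) {
    rlang::abort(sprintf(
      "graph has %d nodes; isomorph generation is k! and limited to k <= %d",
      k, MAX_MOTIF_SIZE))
  }
  eo <- entry_order(k)
  perms <- permutations_of(k)
  keys <- character(nrow(perms))
  labels <- vector("list", nrow(perms))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    lab <- unname(M[p, p, drop = FALSE][eo])
    labels[[i]] <- lab
    keys[i] <- label_key(lab)
  }
  uniq <- !duplicated(keys)
  labels <- labels[uniq]
  labels[order(vapply(labels, label_rank_key, character(1)))]
}

#' Canonical form of a small signed digraph
#'
#' The lexicographically smallest isomorph label under the entry order
#' 0 < +1 < -1; two graphs are isomorphic iff their canonical forms are
#' equal.
#'
#' @inheritParams all_isomorph_labels
#' @return integer label vector of length `k^2`
#' @export
canonical_form <- function(m) {
  all_isomorph_labels(m)[[1]]
}

#' Test isomorphism of two small signed digraphs
#'
#' Signed directed isomorphism: a node bijection must map edges onto edges
#' with identical direction *and* identical sign. Decided by comparing
#' canonical forms (exhaustive over node permutations, exact for
#' `k <= 6`).
#'
#' @param a,b [signed_digraph()]s or square sign matrices
#' @return `TRUE` or `FALSE`
#' @examples
#' g1 <- signed_digraph(data.frame(from = "A", to = "B", sign = 1))
#' g2 <- signed_digraph(data.frame(from = "X", to = "Y", sign = 1))
#' are_isomorphic(g1, g2)
#' @export
are_isomorphic <- function(a, b) {
  Ma <- as_motif_matrix(a); Mb <- as_motif_matrix(b)
  if (nrow(Ma) != nrow(Mb)) return(FALSE)
  identical(canonical_form(Ma), canonical_form(Mb))
}
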