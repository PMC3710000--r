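`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so generators do not perturb user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Fast lookup structure for a signed digraph: dense sign matrix plus sorted
# neighbour lists over integer node indices (1..n, sorted node-id order).
graph_index <- function(g) {
  ids <- g$nodes
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(g$edges) > 0) {
    fi <- match(g$edges$from, ids)
    ti <- match(g$edges$to, ids)
    A[cbind(fi, ti)] <- as.integer(g$edges$sign)
  }
  out_nbrs <- vector("list", n)
  in_nbrs <- vector("list", n)
  und_nbrs <- vector("list", n)
  for (v in seq_len(n)) {
    o <- which(A[v, ] != 0L)
    i <- which(A[, v] != 0L)
    out_nbrs[[v]] <- o[o != v]
    in_nbrs[[v]] <- i[i != v]
    und_nbrs[[v]] <- sort(unique(c(out_nbrs[[v]], in_nbrs[[v]])))
  }
  list(ids = ids, n = n, A = A,
       out_nbrs = out_nbrs, in_nbrs = in_nbrs, und_nbrs = und_nbrs)
}

# All permutations of 1..k as a k! x k integer matrix, lexicographic order.
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(first, rest[sub[j, ]])
    }
  }
  out
}
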