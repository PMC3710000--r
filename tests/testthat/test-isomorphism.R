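test_that("entry order interleaves diagonal, row and column blocks", {
  expect_equal(entry_order(1), cbind(row = 1L, col = 1L))
  expect_equal(entry_order(2),
               cbind(row = c(1L, 2L, 2L, 1L), col = c(1L, 2L, 1L, 2L)))
  expect_equal(entry_order(3),
               cbind(row = c(1L, 2L, 2L, 1L, 3L, 3L, 3L, 1L, 2L),
                     col = c(1L, 2L, 1L, 2L, 3L, 1L, 2L, 3L, 3L)))
  for (k in 1:6) {
    eo <- entry_order(k)
    expect_equal(nrow(eo), k^2)
    # the block contributed by node i has 2i - 1 entries
    contrib <- table(pmax(eo[, 1], eo[, 2]))
    expect_equal(as.integer(contrib), 2L * seq_len(k) - 1L)
    expect_false(anyDuplicated(paste(eo[, 1], eo[, 2])) > 0)
  }
  expect_error(entry_order(0), "positive")
})

test_that("canonical labels read matrices off in entry order, bijectively", {
  expect_equal(canonical_label(rbind(c(0L, 1L), c(-1L, 0L))), c(0L, 0L, -1L, 1L))
  expect_equal(canonical_label(matrix(-1L, 1, 1)), -1L)
  expect_equal(canonical_label(matrix(0L, 3, 3)), rep(0L, 9))
  expect_error(canonical_label(matrix(0L, 2, 3)), "square")
  expect_error(canonical_label(matrix(2L, 1, 1)), "entries")
  # reconstruction round-trip: label -> matrix -> label is the identity
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    M <- matrix(sample(c(-1L, 0L, 1L), k * k, replace = TRUE), k, k)
    lab <- canonical_label(M)
    M2 <- matrix(0L, k, k)
    M2[entry_order(k)] <- lab
    expect_identical(M2, M)
  }
})

test_that("isomorph label counts equal k!/|Aut|", {
  cyc <- cycle_graph(c("A", "B", "C"))           # |Aut| = 3
  expect_length(all_isomorph_labels(cyc), 2)
  chain <- chain_graph(c("A", "B", "C"))         # trivial automorphisms
  expect_length(all_isomorph_labels(chain), 6)
  single <- signed_digraph(NULL, nodes = "A")
  expect_length(all_isomorph_labels(single), 1)
  # label-set size always divides k!
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    g <- random_small_graph(k, loops = TRUE)
    expect_equal(factorial(k) %% length(all_isomorph_labels(g)), 0)
  }
  expect_error(all_isomorph_labels(matrix(0L, 7, 7)), "limited to")
})

test_that("signed isomorphism requires equal signs edge-wise", {
  gp <- signed_digraph(data.frame(from = "A", to = "B", sign = 1))
  gx <- signed_digraph(data.frame(from = "X", to = "Y", sign = 1))
  gn <- signed_digraph(data.frame(from = "X", to = "Y", sign = -1))
  expect_true(are_isomorphic(gp, gx))
  expect_false(are_isomorphic(gp, gn))
  expect_false(are_isomorphic(cycle_graph(c("A", "B", "C")),
                              chain_graph(c("A", "B", "C"))))
})

test_that("canonical forms agree with independent VF2 isomorphism testing", {
  # randomized cross-check on loop-free pairs (igraph VF2 rejects loops)
  set.seed(11)
  n_iso <- 0L
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    a <- random_small_graph(k, p_edge = 0.5)
    b <- if (rep %% 2 == 0) {
      # relabeled copy of a: must be isomorphic
      perm <- sample(a$nodes)
      e <- a$edges
      signed_digraph(data.frame(from = perm[match(e$from, a$nodes)],
                                to = perm[match(e$to, a$nodes)],
                                sign = e$sign), nodes = perm)
    } else {
      random_small_graph(k, p_edge = 0.5)
    }
    expected <- vf2_isomorphic(a, b)
    expect_identical(are_isomorphic(a, b), as.logical(expected))
    n_iso <- n_iso + as.integer(expected)
  }
  expect_gte(n_iso, 20)  # the relabeled copies guarantee both outcomes occur
})

test_that("canonical form is the minimum label and identifies isomorphs", {
  set.seed(5)
  for (rep in 1:15) {
    k <- sample(2:4, 1)
    g <- random_small_graph(k, loops = TRUE)
    labs <- all_isomorph_labels(g)
    keys <- vapply(labs, regmotif:::label_rank_key, character(1))
    expect_identical(canonical_form(g), labs[[which.min(keys)]])
    expect_identical(canonical_form(g), labs[[1]])
  }
})
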