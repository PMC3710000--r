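test_that("ESU yields each connected k-set exactly once", {
  # triangle: a single 3-set
  tri <- cycle_graph(c("a", "b", "c"))
  expect_length(enumerate_connected_subgraphs(tri, 3), 1)
  # directed star: C(3,2) = 3 sets containing the hub; {x,y,z} disconnected
  star <- read_network(c("c + x", "c + y", "c - z"))
  sets <- enumerate_connected_subgraphs(star, 3)
  expect_length(sets, 3)
  expect_true(all(vapply(sets, function(s) "c" %in% s, logical(1))))
  # chain, k = 2: the two edges
  expect_length(enumerate_connected_subgraphs(chain_graph(c("a", "b", "c")), 2), 2)
  expect_error(enumerate_connected_subgraphs(tri, 0), "positive")
})

test_that("ESU agrees with brute-force connected-subset enumeration", {
  set.seed(3)
  for (rep in 1:12) {
    k <- sample(1:4, 1)
    g <- random_small_graph(sample(4:7, 1), p_edge = 0.35, loops = rep %% 3 == 0)
    esu <- lapply(enumerate_connected_subgraphs(g, k), sort)
    keys <- vapply(esu, paste, character(1), collapse = "|")
    expect_false(anyDuplicated(keys) > 0)   # uniqueness
    brute <- regmotif:::all_connected_ksets(g, k)
    expect_setequal(keys, vapply(brute, paste, character(1), collapse = "|"))
  }
})

test_that("find_matches detects induced occurrences only", {
  lib2 <- list(motif("neg2", signed_digraph(
    data.frame(from = c("A", "B"), to = c("B", "A"), sign = c(1L, -1L)))))
  tr <- build_path_tree(lib2)
  g <- read_network(c("A + B", "B - A"))
  m <- find_matches(g, tr)
  expect_equal(nrow(m), 1)
  expect_setequal(m$nodes[[1]], c("A", "B"))
  # a chord breaks induced matching of the positive 3-cycle
  tr3 <- build_path_tree(list(motif("cyc", cycle_graph(c("A", "B", "C")))))
  chord <- signed_digraph(data.frame(from = c("A", "B", "C", "A"),
                                     to = c("B", "C", "A", "C"), sign = 1L))
  expect_equal(nrow(find_matches(chord, tr3)), 0)
  expect_equal(nrow(find_matches(cycle_graph(c("X", "Y", "Z")), tr3)), 1)
})

test_that("matches carry the induced matrix in discovery order", {
  g <- read_network(c("A + B", "B - A", "B + C"))
  tr <- build_path_tree(list(motif("neg2", signed_digraph(
    data.frame(from = c("A", "B"), to = c("B", "A"), sign = c(1L, -1L))))))
  m <- find_matches(g, tr)
  expect_equal(nrow(m), 1)
  M <- m$matrix[[1]]
  expect_identical(unname(M), unname(induced_adjacency(g, m$nodes[[1]])))
  # the discovery-order label sits in the motif's isomorph label set
  neg2 <- signed_digraph(data.frame(from = c("A", "B"), to = c("B", "A"),
                                    sign = c(1L, -1L)))
  keys <- vapply(all_isomorph_labels(neg2), regmotif:::label_key, character(1))
  expect_true(regmotif:::label_key(canonical_label(M)) %in% keys)
})

test_that("search equals the brute-force oracle on random networks", {
  for (seed in 1:5) {
    g <- random_network(18, 36, negative_fraction = 0.3, seed = seed)
    for (k in 2:4) {
      qs <- random_query_motifs(g, k, count = 6, seed = seed + 100)
      tr <- build_path_tree(qs)
      fm <- find_matches(g, tr)
      sk <- oracle_subset_keys(g, k)
      for (i in seq_len(nrow(qs))) {
        got <- sorted_set_list(fm$nodes[fm$motif_id == qs$id[i]])
        want <- oracle_matches(g, qs$motif[[i]], sk)
        expect_identical(got, want,
                         info = sprintf("seed %d k %d motif %s", seed, k, qs$id[i]))
      }
    }
  }
})

test_that("path-tree pruning reduces visited partials without changing results", {
  for (seed in 1:4) {
    g <- random_network(20, 40, negative_fraction = 0.3, seed = seed)
    qs <- random_query_motifs(g, 3, count = 4, seed = seed)
    tr <- build_path_tree(qs)
    pruned <- find_matches(g, tr, prune = TRUE)
    full <- find_matches(g, tr, prune = FALSE)
    key <- function(m) sort(paste(m$motif_id,
                                  vapply(m$nodes, paste, character(1), collapse = "|")))
    expect_identical(key(pruned), key(full))
    expect_lte(attr(pruned, "visits"), attr(full, "visits"))
  }
})

test_that("a node set matches at most one motif of a non-isomorphic library", {
  g <- random_network(20, 50, negative_fraction = 0.3, seed = 9)
  qs <- random_query_motifs(g, 3, count = 10, seed = 9)
  fm <- find_matches(g, build_path_tree(qs))
  per_set <- table(vapply(fm$nodes, function(s) paste(sort(s), collapse = "|"),
                          character(1)))
  expect_true(all(per_set == 1))
})

test_that("count_matches aggregates per motif with zeros included", {
  lib <- builtin_motifs()
  empty <- signed_digraph(NULL, nodes = c("A", "B"))
  ct <- count_matches(empty, lib)
  expect_equal(ct$n_matches, rep(0L, nrow(lib)))
  g <- read_network(c("A + B", "B + A"))
  ct2 <- count_matches(g, lib)
  expect_equal(ct2$n_matches[ct2$motif_id == "bist_mutual_act"], 1L)
  # agreement with oracle counts
  g3 <- random_network(15, 30, negative_fraction = 0.3, seed = 4)
  qs <- random_query_motifs(g3, 3, count = 5, seed = 4)
  ct3 <- count_matches(g3, qs)
  for (i in seq_len(nrow(qs))) {
    expect_equal(ct3$n_matches[ct3$motif_id == qs$id[i]],
                 length(oracle_matches(g3, qs$motif[[i]])))
  }
})
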