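test_that("edge expansion recovers cascades under both constraints", {
  g <- read_network(c("A + B", "B - C", "C + D"))
  ex <- expand_edge(g, "A", "D", -1, eliminated = c("B", "C"))
  expect_equal(nrow(ex), 1)
  expect_equal(ex$path[[1]], c("A", "B", "C", "D"))
  expect_equal(ex$length, 3L)
  expect_equal(ex$sign, -1L)
  # a direct edge of the right sign always qualifies as a length-1 path
  g2 <- read_network(c("A + B", "B - C", "C + D", "A - D"))
  ex2 <- expand_edge(g2, "A", "D", -1, eliminated = c("B", "C"))
  expect_equal(nrow(ex2), 2)
  expect_equal(sort(ex2$length), c(1L, 3L))
  # sign mismatch: no qualifying path
  expect_equal(nrow(expand_edge(g, "A", "D", 1, eliminated = c("B", "C"))), 0)
  # internal nodes must be eliminated
  expect_equal(nrow(expand_edge(g, "A", "D", -1, eliminated = "B")), 0)
})

test_that("length cap and lexicographic ordering are honoured", {
  g <- read_network(c("A + B", "B - C", "C + D", "A - D"))
  ex <- expand_edge(g, "A", "D", -1, eliminated = c("B", "C"), max_len = 2)
  expect_equal(nrow(ex), 1)   # only the direct edge fits
  expect_equal(ex$length, 1L)
  ex2 <- expand_edge(g, "A", "D", -1, eliminated = c("B", "C"), max_len = 8)
  keys <- vapply(ex2$path, paste, character(1), collapse = ">")
  expect_identical(keys, sort(keys))
})

test_that("self-loop expansion recovers collapsed feedback loops", {
  g <- read_network(c("A + B", "B - A"))
  ex <- expand_edge(g, "A", "A", -1, eliminated = "B")
  expect_equal(nrow(ex), 1)
  expect_equal(ex$path[[1]], c("A", "B", "A"))
  expect_equal(ex$length, 2L)
  # direct self-loop as a length-1 recovery
  gl <- read_network("A - A")
  exl <- expand_edge(gl, "A", "A", -1, eliminated = character())
  expect_equal(exl$length, 1L)
})

test_that("instantiation is a disjointness-filtered Cartesian selection", {
  # motif edge (A,B,+) expands 2 ways, (B,A,+) expands 3 ways, no overlaps
  g <- read_network(c(
    "A + B", "A + x1", "x1 + B",          # A->B: direct and via x1
    "B + A", "B + y1", "y1 + A", "B + y2", "y2 + A"))  # B->A: 3 ways
  matches <- tibble::tibble(
    motif_id = "mut_act",
    nodes = list(c("A", "B")),
    matrix = list(induced_adjacency(g, c("A", "B"))))
  inst <- instantiate_matches(matches, g,
                              eliminated = c("x1", "y1", "y2"))
  expect_equal(nrow(inst), 6)
  expect_true(all(inst$motif_id == "mut_act"))
  # sizes: 2 (both direct) up to 4 (both via distinct intermediates)
  expect_equal(sort(unique(inst$size)), c(2L, 3L, 4L))
})

test_that("paths sharing an internal node cannot form one instance", {
  # both motif edges can only expand through the same intermediate X
  g <- read_network(c("A + X", "X + B", "B + X2", "X2 + A"))
  M <- matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  matches <- tibble::tibble(motif_id = "mut_act", nodes = list(c("A", "B")),
                            matrix = list(M))
  inst <- instantiate_matches(matches, g, eliminated = c("X", "X2"))
  expect_equal(nrow(inst), 1)   # distinct intermediates: fine
  g_shared <- read_network(c("A + X", "X + B", "B + X", "X + A"))
  inst2 <- instantiate_matches(matches, g_shared, eliminated = "X")
  expect_equal(nrow(inst2), 0)
  inst3 <- instantiate_matches(matches, g_shared, eliminated = "X",
                               allow_shared_internals = TRUE)
  expect_equal(nrow(inst3), 1)
})

test_that("minimum-size annotation drops undersized realized instances", {
  m <- motif("neg2", signed_digraph(data.frame(from = c("A", "B"),
                                               to = c("B", "A"),
                                               sign = c(1L, -1L))),
             class = "oscillation", min_size = 3)
  g <- read_network(c("A + B", "B - A"))
  matches <- tibble::tibble(motif_id = "neg2", nodes = list(c("A", "B")),
                            matrix = list(induced_adjacency(g, c("A", "B"))))
  # both edges direct: total size 2 < 3, filtered out
  expect_equal(nrow(instantiate_matches(matches, g, motifs = list(m))), 0)
  # a 3-molecule realization passes
  g3 <- read_network(c("A + B", "B + Z", "Z - A"))
  matches3 <- tibble::tibble(motif_id = "neg2", nodes = list(c("A", "B")),
                             matrix = list(matrix(c(0L, 1L, -1L, 0L), 2, 2,
                                                  byrow = TRUE,
                                                  dimnames = list(c("A", "B"),
                                                                  c("A", "B")))))
  inst3 <- instantiate_matches(matches3, g3, eliminated = "Z",
                               motifs = list(m))
  expect_equal(nrow(inst3), 1)
  expect_equal(inst3$size, 3L)
})

test_that("structural properties flatten per-edge sign, length, path and size", {
  g <- read_network(c("A + B", "B - C", "C + D", "D + A"))
  cn <- compress_network(g, protected = c("A", "D"))
  rep <- analyze_network(g, builtin_motifs(), protected = c("A", "D"))
  props <- structural_properties(rep$instances)
  if (nrow(props) > 0) {
    expect_true(all(c("motif_id", "instance", "from", "to", "sign", "length",
                      "path", "size") %in% names(props)))
    expect_true(all(props$sign %in% c(-1L, 1L)))
    expect_true(all(props$length >= 1))
  }
  # a single-edge motif realized through [A,B,C,D]: sign -1, length 3, size 4
  m <- motif("edge", signed_digraph(data.frame(from = "A", to = "D", sign = -1L)))
  matches <- tibble::tibble(motif_id = "edge", nodes = list(c("A", "D")),
                            matrix = list(induced_adjacency(
                              compress_network(read_network(c("A + B", "B - C", "C + D")),
                                               protected = c("A", "D"))$reduced,
                              c("A", "D"))))
  inst <- instantiate_matches(matches, read_network(c("A + B", "B - C", "C + D")),
                              eliminated = c("B", "C"))
  pr <- structural_properties(inst)
  expect_equal(pr$sign, -1L)
  expect_equal(pr$length, 3L)
  expect_equal(pr$size, 4L)
  expect_equal(pr$path, "A>B>C>D")
})

test_that("reported instances exist verbatim in the original network", {
  for (seed in 1:5) {
    g <- random_network(22, 45, negative_fraction = 0.25, seed = seed)
    rep <- analyze_network(g)
    props <- structural_properties(rep$instances)
    idx <- induced_adjacency(g, g$nodes)
    for (i in seq_len(nrow(props))) {
      nodes <- strsplit(props$path[i], ">")[[1]]
      signs <- integer(0)
      for (j in seq_len(length(nodes) - 1)) {
        s <- idx[nodes[j], nodes[j + 1]]
        expect_true(s != 0L)
        signs <- c(signs, s)
      }
      expect_equal(sign_product(signs), props$sign[i])
    }
  }
})
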