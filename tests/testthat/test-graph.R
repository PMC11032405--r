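test_that("constructor validates structure and weights", {
  g <- weighted_graph(1, NULL, weights = 5)
  expect_identical(g$max_degree, 0L)
  expect_identical(n_edges(g), 0L)

  expect_error(weighted_graph(3, rbind(c(2, 2))), "self-loop")
  expect_error(weighted_graph(2, rbind(c(1, 3))), "out of range")
  expect_error(weighted_graph(2, rbind(c(0, 1))), "out of range")
  expect_error(weighted_graph(2, NULL, weights = c(1, 0)), "weights")
  expect_error(weighted_graph(2, NULL, weights = c(1, 1.5)), "weights")
  expect_error(weighted_graph(2, NULL, weights = 1), "length")
  expect_error(weighted_graph(0), "n")

  # duplicate edges (either orientation) are silently merged
  g2 <- weighted_graph(3, rbind(c(1, 2), c(2, 1), c(1, 2), c(2, 3)))
  expect_identical(n_edges(g2), 2L)
  expect_valid_graph(g2)
})

test_that("worked-example graph has the documented degree structure", {
  g <- example_graph()
  expect_identical(degrees(g), c(4L, 3L, 4L, 5L, 4L, 4L, 4L))
  expect_identical(g$max_degree, 5L)
  expect_identical(sort_by_decreasing_degree(g)[1], 4L)
  expect_valid_graph(g)
})

test_that("degree sort is nonincreasing and stable under ties", {
  g <- example_graph()
  # vertex 4 (degree 5) first, the degree-4 block keeps input order, 2 last
  expect_identical(sort_by_decreasing_degree(g), c(4L, 1L, 3L, 5L, 6L, 7L, 2L))

  # regular graph: stability forces the identity order
  cyc <- weighted_graph(5, cbind(1:5, c(2:5, 1)))
  expect_identical(sort_by_decreasing_degree(cyc), 1:5)
  expect_identical(sort_by_decreasing_degree(cyc, c(3L, 1L, 5L)), c(3L, 1L, 5L))

  for (seed in 1:5) {
    g <- rand_g(10, 0.4, seed)
    out <- sort_by_decreasing_degree(g)
    expect_setequal(out, 1:10)
    expect_true(all(diff(degrees(g, out)) <= 0))
  }
  expect_error(sort_by_decreasing_degree(g, c(1, 99)), "out of range")
})

test_that("induced subgraph keeps exactly the internal edges", {
  g <- rand_g(12, 0.5, seed = 11)
  expect_identical(degrees(induced_subgraph(g, 1:12)), degrees(g))

  single <- induced_subgraph(g, 5)
  expect_identical(single$n, 1L)
  expect_identical(degrees(single), 0L)
  expect_identical(vertex_weights(single), vertex_weights(g)[5])

  for (seed in 1:5) {
    g <- rand_g(12, 0.5, seed)
    keep <- sample(12, 6)
    sub <- induced_subgraph(g, keep)
    expect_valid_graph(sub)
    # brute-force filter of the parent edge list
    e <- graph_edges(g)
    inside <- e[e$from %in% keep & e$to %in% keep, ]
    pos <- match(seq_len(g$n), keep)
    expected <- unique(t(apply(cbind(pos[inside$from], pos[inside$to]), 1,
                               sort)))
    got <- as.matrix(graph_edges(sub))
    dimnames(got) <- NULL
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 expected[order(expected[, 1], expected[, 2]), , drop = FALSE])
  }
  expect_error(induced_subgraph(g, integer()), "nonempty")
  expect_error(induced_subgraph(g, c(1, 40)), "out of range")
})

test_that("relabeling preserves structure and round-trips exactly", {
  g <- rand_g(15, 0.4, seed = 2)
  expect_identical(relabel_vertices(g, 1:15), g)

  set.seed(99)
  for (i in 1:10) {
    perm <- sample(15)
    h <- relabel_vertices(g, perm)
    expect_valid_graph(h)
    expect_identical(n_edges(h), n_edges(g))
    expect_identical(sort(degrees(h)), sort(degrees(g)))
    expect_identical(sort(vertex_weights(h)), sort(vertex_weights(g)))
    expect_identical(relabel_vertices(h, order(perm)), g)
  }
  expect_error(relabel_vertices(g, rep(1L, 15)), "permutation")
  expect_error(relabel_vertices(g, 1:14), "permutation")
})

test_that("brute-force optimum is invariant under relabeling", {
  g <- rand_g(15, 0.5, seed = 31)
  ref <- brute_force_mwc(g)$weight
  set.seed(123)
  for (i in 1:20)
    expect_equal(brute_force_mwc(shuffle_vertices(g))$weight, ref)
})
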