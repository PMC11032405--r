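test_that("root coloring of the worked example reproduces the printed trace", {
  g <- example_graph()
  cs <- color_sort_weight(g) # degree-sorted root call, empty Q and Qmax
  expect_identical(cs$classes,
                   list(c(4L, 2L), c(1L, 5L), c(3L, 6L), 7L))
  expect_equal(cs$class_weights, c(7, 8, 5, 1))
  expect_equal(cs$class_bounds, c(7, 15, 20, 21))
  expect_identical(cs$min_k_w, 1L)
  expect_identical(utils::tail(cs$order, 3), c(3L, 6L, 7L))
  expect_equal(wcolor_of(cs, 7), 21)
  expect_equal(wcolor_of(cs, 6), 20)
})

test_that("pruned classes go to the front with bound zero, in input order", {
  g <- example_graph()
  # candidates after branching on vertex 3 at the root: gap = 18 - 5 = 13
  cs <- color_sort_weight(g, c(4, 2, 1, 5), weight_q = 5, weight_qmax = 18)
  expect_identical(cs$order, c(4L, 2L, 1L, 5L))
  expect_equal(cs$wcolor, c(0, 0, 15, 15))
  expect_identical(cs$min_k_w, 2L)
  expect_equal(wcolor_of(cs, 1), 15)
  expect_equal(wcolor_of(cs, 2), 0)
})

test_that("a single vertex forms one class carrying its own weight", {
  g <- weighted_graph(3, rbind(c(1, 2)), weights = c(4, 2, 9))
  cs <- color_sort_weight(g, 3, weight_q = 0, weight_qmax = 0)
  expect_identical(cs$n_classes, 1L)
  expect_identical(cs$min_k_w, 1L)
  expect_equal(cs$wcolor, 9)
})

test_that("classes are independent sets and bounds are sound", {
  for (seed in 1:8) {
    g <- rand_g(18, c(0.3, 0.6, 0.8)[seed %% 3 + 1], seed)
    cs <- color_sort_weight(g)
    # permutation of the input, nondecreasing bounds
    expect_setequal(cs$order, 1:18)
    expect_true(all(diff(cs$wcolor) >= 0))
    # no two adjacent vertices share a class
    A <- adjacency_matrix(g)
    for (cls in cs$classes)
      if (length(cls) > 1) {
        sub <- A[cls, cls]
        expect_false(any(sub[upper.tri(sub)]))
      }
  }
})

test_that("every clique respects the prefix bound of its highest class", {
  for (seed in 1:5) {
    g <- rand_g(12, 0.6, seed)
    cs <- color_sort_weight(g)
    colmap <- integer(12)
    colmap[cs$order] <- cs$color
    for (K in enumerate_cliques(g)) {
      kmax <- max(colmap[K])
      expect_lte(clique_weight(g, K), cs$class_bounds[kmax])
    }
  }
})

test_that("pruning below min_k_w can never discard an improving clique", {
  for (seed in 1:5) {
    g <- rand_g(14, 0.5, seed)
    cliques <- enumerate_cliques(g)
    for (gap in c(50, 150, 400)) {
      cs <- color_sort_weight(g, weight_q = 10, weight_qmax = 10 + gap)
      pruned <- cs$order[cs$wcolor == 0]
      expect_identical(pruned, cs$order[cs$color < cs$min_k_w])
      # a clique lying entirely in pruned classes cannot beat the gap:
      # this is what makes terminating a level at the first zero bound safe
      # (by then every remaining candidate is pruned too)
      within_pruned <- Filter(function(K) all(K %in% pruned), cliques)
      for (K in within_pruned)
        expect_lte(clique_weight(g, K), gap)
    }
  }
})

test_that("with unit weights the bound reduces to the color index", {
  g <- rand_g(15, 0.5, seed = 77)
  g$weights <- rep(1, 15)
  cs <- color_sort_weight(g)
  expect_equal(cs$wcolor, as.numeric(cs$color))
  expect_equal(cs$class_bounds, seq_len(cs$n_classes))
})

test_that("contract violations are rejected", {
  g <- example_graph()
  expect_error(color_sort_weight(g, integer()), "nonempty")
  expect_error(color_sort_weight(g, c(1, 1)), "distinct")
  expect_error(color_sort_weight(g, 1, weight_q = -1), "weight_q")
})
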