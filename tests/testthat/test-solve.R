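test_that("the worked example solves to weight 20 with incumbents 18 then 20", {
  g <- example_graph()
  for (variant in c("static", "dynamic")) {
    res <- solve_mwc(g, variant)
    expect_equal(res$weight, 20)
    expect_identical(res$clique, c(3L, 4L, 5L))
    expect_equal(res$incumbent_history, c(18, 20))
    expect_valid_result(res, g)
  }
  # the two partial-clique weights seen along the winning branch
  w <- vertex_weights(g)
  expect_equal(w[3] + w[1], 7)
  expect_equal(w[3] + w[5], 13)
  # first incumbent is the clique on vertices 4..7
  expect_equal(clique_weight(g, 4:7), 18)
})

test_that("degenerate graphs are handled exactly", {
  k4 <- weighted_graph(4, t(combn(4, 2)), weights = 1:4)
  res <- max_clique_weight(k4)
  expect_equal(res$weight, 10)
  expect_identical(res$clique, 1:4)

  edgeless <- weighted_graph(3, NULL, weights = c(3, 9, 2))
  res <- max_clique_weight(edgeless)
  expect_equal(res$weight, 9)
  expect_identical(res$clique, 2L)

  k1 <- weighted_graph(1, NULL, weights = 6)
  res <- solve_mwc(k1, "static")
  expect_equal(res$weight, 6)
  expect_gte(res$steps_total, 1)
})

test_that("both variants match the brute-force optimum on random graphs", {
  ps <- c(0.2, 0.5, 0.8, 0.9)
  for (i in 1:40) {
    g <- rand_g(8 + i %% 9, ps[i %% 4 + 1], seed = 400 + i)
    ref <- brute_force_mwc(g)$weight
    s <- solve_mwc(g, "static")
    d <- solve_mwc(g, "dynamic")
    expect_equal(s$weight, ref)
    expect_equal(d$weight, ref)
    expect_valid_result(s, g)
    expect_valid_result(d, g)
  }
})

test_that("tlimit = 0 disables reordering: step-for-step identical to static", {
  for (seed in 1:10) {
    g <- rand_g(20 + seed, 0.6, seed = 500 + seed)
    s <- solve_mwc(g, "static")
    d0 <- solve_mwc(g, "dynamic", tlimit = 0)
    expect_identical(d0$clique, s$clique)
    expect_equal(d0$weight, s$weight)
    expect_equal(d0$steps_total, s$steps_total)
    expect_equal(d0$steps_per_level, s$steps_per_level)
  }
})

test_that("optimum weight is invariant under vertex shuffling", {
  g <- rand_g(30, 0.5, seed = 321)
  ref <- max_clique_weight(g)$weight
  set.seed(42)
  for (i in 1:20) {
    gs <- shuffle_vertices(g)
    expect_equal(max_clique_weight(gs)$weight, ref)
    expect_equal(max_clique_dyn_weight(gs)$weight, ref)
  }
})

test_that("with unit weights the solver returns the clique number", {
  for (seed in 1:8) {
    g <- rand_g(12 + seed, 0.5, seed = 600 + seed)
    g$weights <- rep(1, g$n)
    res <- max_clique_weight(g)
    # independent unweighted reference: naive enumeration
    expect_equal(res$weight, brute_force_mwc(g)$size)
    expect_equal(res$weight, res$size)
  }
})

test_that("adding an edge never decreases the optimum", {
  g <- rand_g(10, 0.4, seed = 888)
  base <- max_clique_weight(g)$weight
  A <- adjacency_matrix(g)
  for (u in 1:9) {
    for (v in (u + 1):10) {
      if (A[u, v]) next
      g2 <- weighted_graph(10, rbind(as.matrix(graph_edges(g)), c(u, v)),
                           vertex_weights(g))
      expect_gte(max_clique_weight(g2)$weight, base)
    }
  }
})

test_that("invalid arguments are rejected", {
  g <- example_graph()
  expect_error(solve_mwc(g, "fancy"), "arg")
  expect_error(solve_mwc(g, "dynamic", tlimit = -0.1), "tlimit")
  expect_error(solve_mwc(g, "dynamic", tlimit = 1.5), "tlimit")
  expect_error(solve_mwc(list()), "weighted_graph")
})

test_that("result accessors tidy, glance and autoplot work", {
  g <- example_graph()
  res <- max_clique_weight(g)
  td <- tidy(res, g)
  expect_identical(td$vertex, c(3L, 4L, 5L))
  expect_equal(sum(td$weight), 20)
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$weight, 20)
  expect_identical(gl$variant, "static")
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
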