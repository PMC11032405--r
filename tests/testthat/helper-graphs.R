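# small-weight random graphs keep unit-test failures readable; the
# acceptance suite uses the full-scale weight model (mu 1e6, sigma 2e5)
rand_g <- function(n, p, seed, mu = 100, sigma = 30) {
  random_weighted_graph(n, p, mu = mu, sigma = sigma, seed = seed)
}

clique_weight <- function(g, vs) sum(vertex_weights(g)[vs])

# bound carried by vertex v in a coloring result
wcolor_of <- function(cs, v) cs$wcolor[match(v, cs$order)]

# color class of vertex v in a coloring result
color_of <- function(cs, v) cs$color[match(v, cs$order)]

expect_valid_graph <- function(g) {
  expect_silent(validate_weighted_graph(g))
  expect_identical(sum(degrees(g)), 2L * n_edges(g))
}

# a clique_result must be a genuine clique whose weight recomputes from W
expect_valid_result <- function(res, g) {
  expect_true(is_clique(g, res$clique))
  expect_equal(res$weight, clique_weight(g, res$clique))
  if (length(res$incumbent_history) > 0) {
    expect_true(all(diff(res$incumbent_history) > 0))
    expect_equal(res$incumbent_history[length(res$incumbent_history)],
                 res$weight)
  }
}
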