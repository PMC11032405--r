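#' Draw rounded positive normal vertex weights
#'
#' Weights are sampled from a normal distribution with mean `mu` and standard
#' deviation `sigma`, rounded half-away-from-zero to the nearest integer; any
#' draw that would round below 1 is rejected and redrawn, so every returned
#' weight is a positive integer. At the default scale (`mu = 1e6`,
#' `sigma = 2e5`) rejection is astronomically rare and the returned sample is
#' indistinguishable from the untruncated normal.
#'
#' @param n Number of weights.
#' @param mu Mean of the normal distribution (default 1,000,000).
#' @param sigma Standard deviation (default 200,000; must be > 0).
#' @param seed Optional integer seed; when given, draws are made under a
#'   local RNG state and are reproducible.
#' @return Numeric vector of `n` positive integer-valued weights.
#' @export
draw_weights <- function(n, mu = 1e6, sigma = 2e5, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n %% 1 != 0 || n < 0)
    stop("`n` must be a single nonnegative integer", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("`mu` must be a single number > 0", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single number > 0", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n)
  w <- round_half_up(rnorm(n, mu, sigma))
  bad <- which(w < 1)
  while (length(bad) > 0L) {
    w[bad] <- round_half_up(rnorm(length(bad), mu, sigma))
    bad <- bad[w[bad] < 1]
  }
  w
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Generate a random vertex-weighted graph
#'
#' Erdos-Renyi G(n, p) edges: each unordered vertex pair, taken in the fixed
#' lexicographic order `i < j`, is connected independently when a fresh
#' uniform draw on `[0, 1)` falls below `p`. Vertex weights are then attached
#' with [draw_weights()]. A fixed `seed` fully determines the graph.
#'
#' @param n Number of vertices (>= 1).
#' @param p Edge probability in `[0, 1]`.
#' @param mu,sigma Weight distribution parameters, as in [draw_weights()].
#' @param seed Optional integer seed.
#' @return A [weighted_graph()].
#' @examples
#' g <- random_weighted_graph(50, 0.3, seed = 1)
#' edge_density(g)
#' @export
random_weighted_graph <- function(n, p, mu = 1e6, sigma = 2e5, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n %% 1 != 0 || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  npairs <- n * (n - 1) / 2
  em <- NULL
  if (npairs > 0) {
    hit <- runif(npairs) < p
    if (any(hit)) {
      from <- rep.int(seq_len(n - 1L), (n - 1L):1L)
      to <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n),
                   use.names = FALSE)
      em <- cbind(from[hit], to[hit])
    }
  }
  weighted_graph(n, em, draw_weights(n, mu, sigma))
}

#' Attach fresh random weights to a graph
#'
#' Replaces the weight vector with draws from [draw_weights()], leaving the
#' structure untouched — the procedure used to turn unweighted benchmark
#' instances into weighted ones.
#'
#' @param g A [weighted_graph()].
#' @param mu,sigma,seed As in [draw_weights()].
#' @return A `weighted_graph` with the same edges and new weights.
#' @export
set_random_weights <- function(g, mu = 1e6, sigma = 2e5, seed = NULL) {
  stopifnot_graph(g)
  g$weights <- draw_weights(g$n, mu, sigma, seed = seed)
  g
}

#' Randomly shuffle vertex labels
#'
#' Applies a uniformly random permutation via [relabel_vertices()]: vertex
#' numbers change, structure does not. Shuffling the input is the repeat unit
#' of the benchmarking protocol, because branch-and-bound running times (not
#' results) depend on the initial vertex order.
#'
#' @param g A [weighted_graph()].
#' @param seed Optional integer seed for a reproducible permutation.
#' @return A `weighted_graph` isomorphic to `g`.
#' @export
shuffle_vertices <- function(g, seed = NULL) {
  stopifnot_graph(g)
  if (!is.null(seed)) withr::local_seed(seed)
  relabel_vertices(g, sample.int(g$n))
}

#' The seven-vertex worked-example graph
#'
#' A small weighted graph on vertices 1..7 whose search trace exercises every
#' feature of the algorithm: two incumbent updates (weights 18 then 20),
#' whole-level pruning, and a nontrivial coloring at the root (classes
#' \{4,2\}, \{1,5\}, \{3,6\}, \{7\}). Its maximum weight clique is \{3, 4, 5\}
#' with weight 20. Vertex 4 has degree 5; vertices 1, 3, 5, 6, 7 have degree
#' 4 and vertex 2 degree 3.
#'
#' The weight of vertex 2 is a free parameter: any value in 1..7 leaves the
#' whole trace — every bound, both incumbents and the optimum — unchanged,
#' because vertex 2 shares its color class with the heavier vertex 4 and is
#' always pruned.
#'
#' @param w2 Weight of vertex 2, an integer in 1..7 (default 3).
#' @return A [weighted_graph()] on 7 vertices with 14 edges.
#' @examples
#' max_clique_weight(example_graph())$weight # 20
#' @export
example_graph <- function(w2 = 3) {
  if (!is.numeric(w2) || length(w2) != 1L || is.na(w2) || w2 %% 1 != 0 ||
      w2 < 1 || w2 > 7)
    stop("`w2` must be a single integer in 1..7", call. = FALSE)
  edges <- rbind(
    c(4, 5), c(4, 6), c(4, 7), c(5, 6), c(5, 7), c(6, 7),
    c(1, 6), c(1, 3), c(1, 2), c(1, 4), c(2, 3), c(2, 7),
    c(3, 4), c(3, 5)
  )
  weighted_graph(7, edges, weights = c(2, w2, 5, 7, 8, 2, 1))
}
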