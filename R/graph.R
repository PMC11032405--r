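#' Construct a vertex-weighted undirected graph
#'
#' The central data structure of the package: `n` vertices identified `1..n`,
#' a symmetric loop-free adjacency, and a positive integer weight per vertex.
#' Duplicate edges (in either orientation) are silently deduplicated;
#' self-loops are an error, because clique semantics are undefined on loops.
#'
#' @param n Number of vertices (>= 1).
#' @param edges Edge list: a two-column matrix or data frame of vertex ids in
#'   `1..n`, or `NULL` for an edgeless graph.
#' @param weights Numeric vector of positive integer vertex weights, length
#'   `n` (default: all 1). Values must be whole numbers `>= 1`; they are kept
#'   as doubles, which is exact far beyond the `n * 2e6` range the random
#'   weight model produces.
#'
#' @return An object of class `weighted_graph`: a list with elements `n`,
#'   `adj` (per-vertex sorted integer neighbor vectors), `weights`, and
#'   `max_degree`.
#' @examples
#' g <- weighted_graph(3, rbind(c(1, 2), c(2, 3)), weights = c(5, 1, 2))
#' degrees(g)
#' @export
weighted_graph <- function(n, edges = NULL, weights = rep(1, n)) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n %% 1 != 0 || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)

  if (!is.numeric(weights) || length(weights) != n)
    stop("`weights` must be a numeric vector of length n = ", n, call. = FALSE)
  if (anyNA(weights) || any(weights %% 1 != 0) || any(weights < 1))
    stop("all vertex weights must be integers >= 1", call. = FALSE)
  weights <- as.numeric(weights)

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(), ncol = 2L)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (!is.matrix(edges) || ncol(edges) != 2L || !is.numeric(edges))
      stop("`edges` must be a two-column numeric matrix or data frame",
           call. = FALSE)
    if (anyNA(edges) || any(edges %% 1 != 0))
      stop("edge endpoints must be whole numbers", call. = FALSE)
    if (any(edges < 1) || any(edges > n))
      stop("edge endpoint out of range 1..", n, call. = FALSE)
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed", call. = FALSE)
    em <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    em <- unique(em)
    storage.mode(em) <- "integer"
  }

  adj <- rep(list(integer()), n)
  if (nrow(em) > 0L) {
    nb <- split(c(em[, 2], em[, 1]), factor(c(em[, 1], em[, 2]), levels = 1:n))
    adj <- lapply(nb, function(x) sort(as.integer(x)))
    names(adj) <- NULL
  }

  structure(
    list(n = n, adj = adj, weights = weights,
         max_degree = if (n > 0) max(lengths(adj)) else 0L),
    class = "weighted_graph"
  )
}

#' Test for the weighted_graph class
#' @param x Object.
#' @return Logical scalar.
#' @export
is_weighted_graph <- function(x) inherits(x, "weighted_graph")

stopifnot_graph <- function(g) {
  if (!is_weighted_graph(g))
    stop("expected a `weighted_graph` object", call. = FALSE)
  invisible(g)
}

check_vertices <- function(g, vertices, allow_empty = FALSE) {
  if (!is.numeric(vertices) || anyNA(vertices) || any(vertices %% 1 != 0))
    stop("vertex ids must be whole numbers", call. = FALSE)
  if (!allow_empty && length(vertices) == 0L)
    stop("vertex set must be nonempty", call. = FALSE)
  if (any(vertices < 1) || any(vertices > g$n))
    stop("vertex id out of range 1..", g$n, call. = FALSE)
  if (anyDuplicated(vertices))
    stop("vertex ids must be distinct", call. = FALSE)
  as.integer(vertices)
}

#' Assert the structural invariants of a weighted graph
#'
#' Checks adjacency symmetry, absence of self-loops, weight positivity and
#' integrality, and the cached maximum degree. Used by the test suite on every
#' constructed graph.
#'
#' @param g A `weighted_graph`.
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_weighted_graph <- function(g) {
  stopifnot_graph(g)
  if (length(g$adj) != g$n) stop("adjacency length != n", call. = FALSE)
  for (v in seq_len(g$n)) {
    nb <- g$adj[[v]]
    if (any(nb == v)) stop("self-loop at vertex ", v, call. = FALSE)
    if (anyDuplicated(nb)) stop("duplicate neighbor at vertex ", v, call. = FALSE)
    for (u in nb)
      if (!(v %in% g$adj[[u]]))
        stop("asymmetric adjacency: ", v, " -> ", u, call. = FALSE)
  }
  if (length(g$weights) != g$n || any(g$weights < 1) || any(g$weights %% 1 != 0))
    stop("invalid weight vector", call. = FALSE)
  if (g$max_degree != max(c(0L, lengths(g$adj))))
    stop("stale max_degree cache", call. = FALSE)
  invisible(g)
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf(
    "<weighted_graph> %d vertices, %d edges, max degree %d, total weight %s\n",
    x$n, n_edges(x), x$max_degree, format(sum(x$weights), scientific = FALSE)))
  invisible(x)
}

#' Vertex degrees
#' @param g A `weighted_graph`.
#' @param vertices Vertex ids (default all).
#' @return Integer vector of degrees.
#' @export
degrees <- function(g, vertices = seq_len(g$n)) {
  stopifnot_graph(g)
  vertices <- check_vertices(g, vertices, allow_empty = TRUE)
  lengths(g$adj)[vertices]
}

#' Number of vertices
#' @param g A `weighted_graph`.
#' @return Integer scalar.
#' @export
n_vertices <- function(g) {
  stopifnot_graph(g)
  g$n
}

#' Number of edges
#' @param g A `weighted_graph`.
#' @return Integer scalar.
#' @export
n_edges <- function(g) {
  stopifnot_graph(g)
  as.integer(sum(lengths(g$adj)) / 2)
}

#' Vertex weights
#' @param g A `weighted_graph`.
#' @return Numeric vector of length `n_vertices(g)`.
#' @export
vertex_weights <- function(g) {
  stopifnot_graph(g)
  g$weights
}

#' Edge density
#' @param g A `weighted_graph`.
#' @return Edge count divided by `choose(n, 2)`; 0 for a single vertex.
#' @export
edge_density <- function(g) {
  stopifnot_graph(g)
  if (g$n < 2) return(0)
  n_edges(g) / choose(g$n, 2)
}

#' Edge list as a tibble
#' @param g A `weighted_graph`.
#' @return A tibble with integer columns `from` and `to` (`from < to`).
#' @export
graph_edges <- function(g) {
  stopifnot_graph(g)
  from <- rep.int(seq_len(g$n), lengths(g$adj))
  to <- unlist(g$adj, use.names = FALSE)
  keep <- from < to
  tibble::tibble(from = from[keep], to = as.integer(to[keep]))
}

#' Sort vertices by decreasing degree
#'
#' Stable sort: vertices of equal degree keep their relative order in the
#' input sequence. This is the root ordering of the branch-and-bound search;
#' the stability rule is what makes the search deterministic.
#'
#' @param g A `weighted_graph`.
#' @param vertices Ordered vertex sequence to sort (default all, `1..n`).
#' @return A permutation of `vertices` with nonincreasing degree in `g`.
#' @export
sort_by_decreasing_degree <- function(g, vertices = seq_len(g$n)) {
  stopifnot_graph(g)
  vertices <- check_vertices(g, vertices)
  deg <- lengths(g$adj)[vertices]
  vertices[order(-deg, seq_along(vertices))]
}

#' Induced subgraph
#'
#' Restricts the graph to a vertex subset, keeping exactly the edges internal
#' to it. Vertices are renumbered `1..length(vertices)` in the order given;
#' the original ids are attached as the `"vertex_map"` attribute.
#'
#' @param g A `weighted_graph`.
#' @param vertices Distinct vertex ids to keep (nonempty).
#' @return A `weighted_graph` on `length(vertices)` vertices.
#' @export
induced_subgraph <- function(g, vertices) {
  stopifnot_graph(g)
  vertices <- check_vertices(g, vertices)
  pos <- integer(g$n)
  pos[vertices] <- seq_along(vertices)
  adj <- lapply(vertices, function(v) {
    nb <- g$adj[[v]]
    sort(pos[nb[pos[nb] > 0L]])
  })
  out <- structure(
    list(n = length(vertices), adj = adj,
         weights = g$weights[vertices],
         max_degree = max(c(0L, lengths(adj)))),
    class = "weighted_graph"
  )
  attr(out, "vertex_map") <- vertices
  out
}

#' Relabel vertices by a permutation
#'
#' Produces the isomorphic graph in which vertex `v` becomes `perm[v]`.
#' Structure is untouched: edge count, degree multiset and weight multiset
#' are preserved, and `relabel_vertices(relabel_vertices(g, p), order(p))`
#' returns the original graph.
#'
#' @param g A `weighted_graph`.
#' @param perm An integer permutation of `1..n_vertices(g)`.
#' @return A `weighted_graph`.
#' @export
relabel_vertices <- function(g, perm) {
  stopifnot_graph(g)
  if (!is.numeric(perm) || length(perm) != g$n || anyNA(perm) ||
      any(perm %% 1 != 0) || !setequal(perm, seq_len(g$n)))
    stop("`perm` must be a permutation of 1..", g$n, call. = FALSE)
  perm <- as.integer(perm)
  adj <- vector("list", g$n)
  weights <- numeric(g$n)
  for (v in seq_len(g$n)) {
    adj[[perm[v]]] <- sort(perm[g$adj[[v]]])
    weights[perm[v]] <- g$weights[v]
  }
  structure(
    list(n = g$n, adj = adj, weights = weights, max_degree = g$max_degree),
    class = "weighted_graph"
  )
}

# 0-based adjacency list for the .Call boundary
adj0 <- function(g) lapply(g$adj, function(x) x - 1L)
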