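#' Brute-force maximum weight clique reference
#'
#' A deliberately naive exact solver used to verify the branch-and-bound
#' search: it enumerates cliques with no weighted bound of any kind (no
#' coloring, no pruning beyond adjacency) and keeps the heaviest. Two
#' independent strategies are provided so the reference itself can be
#' cross-validated: `"recursion"` walks every clique once by extending with
#' later candidates; `"subsets"` scans all `2^n` vertex subsets and is
#' restricted to `n <= 15`. The implementation is pure R and shares no code
#' with the branch-and-bound path.
#'
#' @param g A [weighted_graph()].
#' @param method `"recursion"` (default) or `"subsets"`.
#' @param max_n Refuse graphs larger than this (default 30 for
#'   `"recursion"`, hard-capped at 15 for `"subsets"`): enumeration is
#'   exponential and the guard prevents accidental blowups.
#' @return A `clique_result` with `variant = "brute-force"`; step counters
#'   and incumbent history are not tracked.
#' @examples
#' brute_force_mwc(example_graph())$weight # 20
#' @export
brute_force_mwc <- function(g, method = c("recursion", "subsets"),
                            max_n = 30) {
  stopifnot_graph(g)
  method <- match.arg(method)
  limit <- if (method == "subsets") min(max_n, 15) else max_n
  if (g$n > limit)
    stop("graph has ", g$n, " vertices; brute force is guarded at ", limit,
         call. = FALSE)
  res <- if (method == "recursion") bf_recursion(g) else bf_subsets(g)
  structure(
    list(
      clique = sort(res$clique),
      weight = res$weight,
      size = length(res$clique),
      steps_total = NA_real_,
      steps_per_level = numeric(),
      incumbent_history = numeric(),
      variant = "brute-force",
      tlimit = NA_real_,
      n = g$n,
      density = edge_density(g)
    ),
    class = "clique_result"
  )
}

bf_recursion <- function(g) {
  A <- adjacency_matrix(g)
  w <- g$weights
  best_w <- 0
  best <- integer()
  rec <- function(clique, wsum, cand) {
    if (wsum > best_w) {
      best_w <<- wsum
      best <<- clique
    }
    while (length(cand) > 0L) {
      v <- cand[[1L]]
      cand <- cand[-1L]
      rec(c(clique, v), wsum + w[[v]], cand[A[v, cand]])
    }
  }
  rec(integer(), 0, seq_len(g$n))
  list(clique = best, weight = best_w)
}

bf_subsets <- function(g) {
  A <- adjacency_matrix(g)
  w <- g$weights
  n <- g$n
  bits <- 2^(seq_len(n) - 1L)
  best_w <- 0
  best <- integer()
  for (s in seq_len(2^n - 1)) {
    members <- which(bitwAnd(s, bits) > 0)
    if (length(members) > 1L) {
      sub <- A[members, members, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) next
    }
    wsum <- sum(w[members])
    if (wsum > best_w) {
      best_w <- wsum
      best <- members
    }
  }
  list(clique = best, weight = best_w)
}

#' Enumerate every clique of a small graph
#'
#' Plain recursive enumeration of all nonempty cliques, used by the test
#' suite to verify the coloring bound and prune-safety exhaustively.
#'
#' @param g A [weighted_graph()].
#' @param max_n Guard on graph size (default 20).
#' @return A list of integer vectors, each a clique (vertices in increasing
#'   order).
#' @export
enumerate_cliques <- function(g, max_n = 20) {
  stopifnot_graph(g)
  if (g$n > max_n)
    stop("graph has ", g$n, " vertices; enumeration is guarded at ", max_n,
         call. = FALSE)
  A <- adjacency_matrix(g)
  out <- vector("list", 0L)
  rec <- function(clique, cand) {
    if (length(clique) > 0L) out[[length(out) + 1L]] <<- clique
    while (length(cand) > 0L) {
      v <- cand[[1L]]
      cand <- cand[-1L]
      rec(c(clique, v), cand[A[v, cand]])
    }
  }
  rec(integer(), seq_len(g$n))
  out
}

#' Logical adjacency matrix
#' @param g A [weighted_graph()].
#' @return An `n x n` symmetric logical matrix with `FALSE` diagonal.
#' @export
adjacency_matrix <- function(g) {
  stopifnot_graph(g)
  A <- matrix(FALSE, g$n, g$n)
  for (v in seq_len(g$n)) A[v, g$adj[[v]]] <- TRUE
  A
}

#' Check that a vertex set is a clique
#' @param g A [weighted_graph()].
#' @param vertices Vertex ids.
#' @return Logical scalar: `TRUE` iff every pair is adjacent.
#' @export
is_clique <- function(g, vertices) {
  stopifnot_graph(g)
  vertices <- check_vertices(g, vertices, allow_empty = TRUE)
  if (length(vertices) < 2L) return(TRUE)
  A <- adjacency_matrix(g)
  sub <- A[vertices, vertices, drop = FALSE]
  all(sub[upper.tri(sub)])
}
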