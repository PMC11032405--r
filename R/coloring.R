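#' Weighted greedy coloring with cumulative clique-weight bounds
#'
#' The bounding procedure of the branch-and-bound search. The candidate
#' vertices are scanned in their incoming order and each is placed in the
#' lowest-indexed color class containing none of its neighbors, opening a new
#' class when needed; each class records the maximum weight of its vertices.
#' Any clique inside `vertices` holds at most one vertex per class, so a
#' clique whose highest class index is `k` weighs at most
#' `ub_k = sum(class_weights[1:k])` — the cumulative bound (`wcolor`)
#' assigned to every vertex of class `k`.
#'
#' Classes whose prefix bound cannot close the gap between the incumbent
#' weight (`weight_qmax`) and the growing clique weight (`weight_q`) are
#' pruned: `min_k_w` is the smallest `k` with `ub_k > weight_qmax - weight_q`
#' (or `n_classes + 1` when none qualifies). Vertices of lower classes are
#' moved to the front of the output in their incoming relative order and
#' carry `wcolor = 0`; the remaining classes follow in class order, each
#' vertex carrying `ub_k`. The output `wcolor` sequence is therefore
#' nondecreasing, which lets the search stop a whole level at the first
#' failing bound test.
#'
#' @param g A [weighted_graph()].
#' @param vertices Ordered candidate sequence (nonempty, distinct ids).
#'   Defaults to all vertices sorted by decreasing degree — the root call of
#'   the search.
#' @param weight_q Weight of the clique grown so far (>= 0).
#' @param weight_qmax Weight of the best clique found so far (>= 0).
#' @return An object of class `mwc_coloring`: list with `order`, `wcolor`,
#'   `color` (class per output position), `min_k_w`, `n_classes`, `classes`
#'   (list of integer vectors in insertion order), `class_weights`, and
#'   `class_bounds` (the prefix sums `ub_k`).
#' @examples
#' g <- example_graph()
#' cs <- color_sort_weight(g)
#' cs$wcolor[match(7, cs$order)] # bound carried by vertex 7 at the root
#' @export
color_sort_weight <- function(g, vertices = sort_by_decreasing_degree(g),
                              weight_q = 0, weight_qmax = 0) {
  stopifnot_graph(g)
  vertices <- check_vertices(g, vertices)
  for (nm in c("weight_q", "weight_qmax")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < 0)
      stop("`", nm, "` must be a single number >= 0", call. = FALSE)
  }
  out <- csw_cpp(adj0(g), g$weights, vertices - 1L, weight_q, weight_qmax)
  out$weight_q <- weight_q
  out$weight_qmax <- weight_qmax
  class(out) <- "mwc_coloring"
  out
}

#' @export
print.mwc_coloring <- function(x, ...) {
  cat(sprintf("<mwc_coloring> %d vertices in %d classes, min_k_w = %d\n",
              length(x$order), x$n_classes, x$min_k_w))
  cat("order: ", paste(x$order, collapse = " "), "\n")
  cat("wcolor:", paste(format(x$wcolor, scientific = FALSE, trim = TRUE),
                       collapse = " "), "\n")
  invisible(x)
}

#' @describeIn color_sort_weight Tidy the reordered candidate set: one row
#'   per output position with the vertex, its color class and its bound.
#' @param x An `mwc_coloring` object.
#' @param ... Unused.
#' @export
tidy.mwc_coloring <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$order),
    vertex = as.integer(x$order),
    color = as.integer(x$color),
    wcolor = as.numeric(x$wcolor)
  )
}
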