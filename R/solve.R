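#' Find a maximum weight clique exactly
#'
#' Branch-and-bound search over the clique lattice. Vertices are first sorted
#' by decreasing degree (stable), an initial weighted greedy coloring assigns
#' every vertex a cumulative weight bound ([color_sort_weight()]), and the
#' recursive expansion then repeatedly selects the candidate with the highest
#' bound (the last in the reordered sequence): a branch is explored only when
#' `weight(Q) + wcolor(p) > weight(Qmax)`; because bounds are nondecreasing
#' along the candidate order, the first failure terminates the whole level.
#' The search is exact — the returned weight is the true optimum — and fully
#' deterministic for a fixed input vertex order.
#'
#' The dynamic variant additionally recomputes, at search levels where the
#' fraction `T[level]` of expansion steps spent at depths `1..level` is below
#' `tlimit`, the degrees of the candidates within their induced subgraph and
#' re-sorts them (stably) by decreasing induced degree before coloring. This
#' tightens the bounds where candidate sets are large — the lower recursion
#' levels — at an `O(|Rp|^2)` cost per recomputation. With `tlimit = 0` the
#' gate never fires and the dynamic variant is step-for-step identical to the
#' static one; both always return the same optimal weight.
#'
#' @param g A [weighted_graph()].
#' @param variant `"static"` (bounds fixed at the root ordering) or
#'   `"dynamic"` (induced-degree reordering gated by `tlimit`).
#' @param tlimit Step-fraction threshold in `[0, 1]` for the dynamic variant;
#'   default 0.025, which confines reordering to the lowest levels.
#' @return An object of class `clique_result`: list with `clique` (sorted
#'   vertex ids), `weight`, `size`, `steps_total`, `steps_per_level`,
#'   `incumbent_history` (strictly increasing, ending at `weight`),
#'   `variant`, `tlimit`, `n`, and `density`.
#' @examples
#' g <- example_graph()
#' res <- max_clique_weight(g)
#' res$weight # 20
#' res$clique # 3 4 5
#' @export
solve_mwc <- function(g, variant = c("static", "dynamic"), tlimit = 0.025) {
  stopifnot_graph(g)
  variant <- match.arg(variant)
  dyn <- variant == "dynamic"
  if (dyn) {
    if (!is.numeric(tlimit) || length(tlimit) != 1L || is.na(tlimit) ||
        tlimit < 0 || tlimit > 1)
      stop("`tlimit` must be a single number in [0, 1]", call. = FALSE)
  }
  root <- sort_by_decreasing_degree(g)
  raw <- mwc_cpp(adj0(g), g$weights, root - 1L, dyn,
                 if (dyn) tlimit else 0)
  structure(
    list(
      clique = sort(as.integer(raw$clique)),
      weight = raw$weight,
      size = length(raw$clique),
      steps_total = raw$steps_total,
      steps_per_level = raw$steps_per_level,
      incumbent_history = raw$incumbent_history,
      variant = variant,
      tlimit = if (dyn) tlimit else NA_real_,
      n = g$n,
      density = edge_density(g)
    ),
    class = "clique_result"
  )
}

#' @rdname solve_mwc
#' @export
max_clique_weight <- function(g) solve_mwc(g, "static")

#' @rdname solve_mwc
#' @export
max_clique_dyn_weight <- function(g, tlimit = 0.025)
  solve_mwc(g, "dynamic", tlimit = tlimit)

#' @export
print.clique_result <- function(x, ...) {
  cat(sprintf("<clique_result> weight %s, %d vertices (%s)\n",
              format(x$weight, scientific = FALSE), x$size, x$variant))
  cat("clique:", paste(x$clique, collapse = " "), "\n")
  if (!is.null(x$steps_total) && !is.na(x$steps_total))
    cat(sprintf("steps: %s; incumbents: %s\n",
                format(x$steps_total, scientific = FALSE),
                paste(format(x$incumbent_history, scientific = FALSE,
                             trim = TRUE), collapse = " ")))
  invisible(x)
}

#' Tidy a clique result
#'
#' One row per clique member with its weight.
#'
#' @param x A `clique_result`.
#' @param g Optional `weighted_graph` the result came from; when supplied the
#'   per-vertex weights are included.
#' @param ... Unused.
#' @return A tibble with columns `vertex` and (when `g` is given) `weight`.
#' @export
tidy.clique_result <- function(x, g = NULL, ...) {
  out <- tibble::tibble(vertex = x$clique)
  if (!is.null(g)) {
    stopifnot_graph(g)
    out$weight <- g$weights[x$clique]
  }
  out
}

#' Glance at a clique result
#'
#' @param x A `clique_result`.
#' @param ... Unused.
#' @return A one-row tibble: `weight`, `size`, `steps_total`, `n_incumbents`,
#'   `variant`, `tlimit`, `n`, `density`.
#' @export
glance.clique_result <- function(x, ...) {
  tibble::tibble(
    weight = x$weight,
    size = x$size,
    steps_total = if (is.null(x$steps_total)) NA_real_ else x$steps_total,
    n_incumbents = length(x$incumbent_history),
    variant = x$variant,
    tlimit = x$tlimit,
    n = x$n,
    density = x$density
  )
}

#' Plot the incumbent-weight history of a search
#'
#' Step plot of the best clique weight found against the order of incumbent
#' updates — the classic anytime profile of a branch-and-bound run.
#'
#' @param object A `clique_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clique_result <- function(object, ...) {
  df <- tibble::tibble(
    update = seq_along(object$incumbent_history),
    weight = as.numeric(object$incumbent_history)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$update, y = .data$weight)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Incumbent update",
      y = "Clique weight",
      title = sprintf("Incumbent history (%s variant)", object$variant)
    )
}

#' @importFrom ggplot2 .data
NULL
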