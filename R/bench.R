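#' Shuffle-and-repeat benchmarking of clique solvers
#'
#' Runs each solver on each graph `repeats` times, each repeat on a freshly
#' vertex-shuffled copy (structure preserved, labels permuted), and reports
#' mean and sample standard deviation of the elapsed wall time together with
#' the optimum found and whether every repeat agreed on it — the protocol
#' under which branch-and-bound timings are meaningfully comparable, since
#' running time (never the result) depends on the initial vertex order. All
#' solvers see the same sequence of shuffled instances.
#'
#' @param graphs A single [weighted_graph()] or a (preferably named) list of
#'   them.
#' @param algorithms Character vector drawn from `"static"` and `"dynamic"`,
#'   and/or a named list of solver functions `function(g) -> list(weight=...)`
#'   — the hook for benchmarking an external reference solver.
#' @param repeats Number of repeats per (graph, algorithm) pair (>= 1).
#' @param shuffle Shuffle vertex labels before each repeat (default `TRUE`).
#' @param seed Optional integer seed making the shuffle sequence reproducible.
#' @param reference Optional name of one entry of `algorithms`; when given, a
#'   `speedup` column reports `mean time(reference) / mean time(algorithm)`.
#' @param tlimit Threshold for the `"dynamic"` variant.
#' @param floor_s,cap_s Optional lower/upper caps applied to the per-run
#'   times before averaging (cosmetic reporting parity with capped published
#'   tables; off by default).
#' @return A tibble with one row per (graph, algorithm):
#'   `instance`, `n`, `density`, `algorithm`, `repeats`, `mean_s`, `sd_s`,
#'   `weight`, `agree`, and optionally `speedup`.
#' @export
run_benchmark <- function(graphs, algorithms = c("static", "dynamic"),
                          repeats = 100, shuffle = TRUE, seed = NULL,
                          reference = NULL, tlimit = 0.025,
                          floor_s = NULL, cap_s = NULL) {
  if (is_weighted_graph(graphs)) graphs <- list(graphs)
  if (!is.list(graphs) || length(graphs) == 0L ||
      !all(vapply(graphs, is_weighted_graph, logical(1))))
    stop("`graphs` must be one weighted_graph or a list of them", call. = FALSE)
  if (is.null(names(graphs)) || any(names(graphs) == ""))
    names(graphs) <- paste0("graph", seq_along(graphs))
  if (!is.numeric(repeats) || length(repeats) != 1L || is.na(repeats) ||
      repeats %% 1 != 0 || repeats < 1)
    stop("`repeats` must be a single integer >= 1", call. = FALSE)
  repeats <- as.integer(repeats)

  solvers <- resolve_algorithms(algorithms, tlimit)
  if (length(solvers) == 0L)
    stop("at least one algorithm is required", call. = FALSE)
  if (!is.null(reference) && !reference %in% names(solvers))
    stop("`reference` must name one of the algorithms", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  rows <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    inputs <- lapply(seq_len(repeats), function(r) {
      if (shuffle && g$n > 1) relabel_vertices(g, sample.int(g$n)) else g
    })
    for (ai in seq_along(solvers)) {
      fn <- solvers[[ai]]
      times <- numeric(repeats)
      weights <- numeric(repeats)
      for (r in seq_len(repeats)) {
        t0 <- proc.time()[["elapsed"]]
        res <- fn(inputs[[r]])
        times[r] <- proc.time()[["elapsed"]] - t0
        weights[r] <- res$weight
      }
      if (!is.null(floor_s)) times <- pmax(times, floor_s)
      if (!is.null(cap_s)) times <- pmin(times, cap_s)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        instance = names(graphs)[gi],
        n = g$n,
        density = edge_density(g),
        algorithm = names(solvers)[ai],
        repeats = repeats,
        mean_s = mean(times),
        sd_s = if (repeats > 1L) sd(times) else 0,
        weight = weights[1],
        agree = all(weights == weights[1])
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    ref_mean <- out$mean_s[out$algorithm == reference]
    names(ref_mean) <- out$instance[out$algorithm == reference]
    out$speedup <- ref_mean[out$instance] / out$mean_s
    names(out$speedup) <- NULL
  }
  out
}

resolve_algorithms <- function(algorithms, tlimit) {
  named <- function(name) {
    switch(name,
      static = function(g) solve_mwc(g, "static"),
      dynamic = function(g) solve_mwc(g, "dynamic", tlimit = tlimit),
      stop("unknown algorithm `", name, "` (use \"static\", \"dynamic\", ",
           "or supply a function)", call. = FALSE)
    )
  }
  if (is.character(algorithms)) {
    out <- lapply(algorithms, named)
    names(out) <- algorithms
    return(out)
  }
  if (is.function(algorithms)) algorithms <- list(custom = algorithms)
  if (!is.list(algorithms))
    stop("`algorithms` must be a character vector or list", call. = FALSE)
  out <- vector("list", length(algorithms))
  nm <- names(algorithms)
  if (is.null(nm)) nm <- rep("", length(algorithms))
  for (i in seq_along(algorithms)) {
    a <- algorithms[[i]]
    if (is.character(a) && length(a) == 1L) {
      out[[i]] <- named(a)
      if (nm[i] == "") nm[i] <- a
    } else if (is.function(a)) {
      out[[i]] <- a
      if (nm[i] == "") nm[i] <- paste0("custom", i)
    } else {
      stop("each algorithm must be a name or a function", call. = FALSE)
    }
  }
  names(out) <- nm
  out
}

bench_columns <- c("instance", "n", "density", "algorithm", "repeats",
                   "mean_s", "sd_s", "weight", "agree")

#' Write benchmark records to CSV
#'
#' Fixed header `instance,n,density,algorithm,repeats,mean_s,sd_s,weight,agree`
#' (plus `speedup` when present); [read_bench_csv()] round-trips the records.
#'
#' @param records Tibble from [run_benchmark()].
#' @param path Output file path.
#' @return `records`, invisibly.
#' @export
write_bench_csv <- function(records, path) {
  if (!is.data.frame(records) || !all(bench_columns %in% names(records)))
    stop("`records` must be a benchmark tibble", call. = FALSE)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' @rdname write_bench_csv
#' @export
read_bench_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(bench_columns %in% names(df)))
    stop("`", path, "` is not a benchmark CSV", call. = FALSE)
  tibble::as_tibble(df)
}
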