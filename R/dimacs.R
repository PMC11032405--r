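#' Read a graph in ASCII DIMACS clique format
#'
#' Parses the plain-text benchmark format of the DIMACS implementation
#' challenges: comment lines `c ...`, one problem line `p edge <n> <m>`
#' (`p col` accepted as a synonym), and edge lines `e <i> <j>` with 1-based
#' endpoints. Vertex weights use the sidecar-free dialect `v <i> <w>`; a file
#' without `v` lines is a valid unweighted instance and every weight defaults
#' to 1. Duplicate edge lines (either orientation) are deduplicated silently;
#' `e` and `v` lines may appear in any order after the problem line.
#'
#' @param x Path to a DIMACS file, `"-"` for standard input, or a character
#'   vector containing the document itself (detected by embedded newlines or
#'   length > 1).
#' @return A [weighted_graph()].
#' @seealso [write_dimacs()]
#' @export
read_dimacs <- function(x) {
  lines <- dimacs_lines(x)
  n <- NULL
  edges <- list()
  wmap <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "c")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    kind <- tok[[1]]
    if (kind == "p") {
      if (!is.null(n))
        stop("DIMACS line ", i, ": second problem line", call. = FALSE)
      if (length(tok) != 4L || !(tok[[2]] %in% c("edge", "col")))
        stop("DIMACS line ", i, ": malformed problem line (want `p edge n m`)",
             call. = FALSE)
      n <- dimacs_int(tok[[3]], i)
      if (n < 1)
        stop("DIMACS line ", i, ": vertex count must be >= 1", call. = FALSE)
    } else if (kind == "e") {
      if (is.null(n))
        stop("DIMACS line ", i, ": edge line before problem line", call. = FALSE)
      if (length(tok) != 3L)
        stop("DIMACS line ", i, ": malformed edge line", call. = FALSE)
      u <- dimacs_int(tok[[2]], i)
      v <- dimacs_int(tok[[3]], i)
      if (u < 1 || u > n || v < 1 || v > n)
        stop("DIMACS line ", i, ": endpoint out of range 1..", n, call. = FALSE)
      if (u == v)
        stop("DIMACS line ", i, ": self-loop", call. = FALSE)
      edges[[length(edges) + 1L]] <- c(u, v)
    } else if (kind == "v") {
      if (is.null(n))
        stop("DIMACS line ", i, ": weight line before problem line", call. = FALSE)
      if (length(tok) != 3L)
        stop("DIMACS line ", i, ": malformed weight line", call. = FALSE)
      u <- dimacs_int(tok[[2]], i)
      w <- dimacs_int(tok[[3]], i)
      if (u < 1 || u > n)
        stop("DIMACS line ", i, ": vertex out of range 1..", n, call. = FALSE)
      if (w < 1)
        stop("DIMACS line ", i, ": weight must be >= 1", call. = FALSE)
      key <- as.character(u)
      if (!is.null(wmap[[key]]))
        stop("DIMACS line ", i, ": duplicate weight line for vertex ", u,
             call. = FALSE)
      wmap[[key]] <- w
    } else {
      stop("DIMACS line ", i, ": unknown line type `", kind, "`", call. = FALSE)
    }
  }
  if (is.null(n))
    stop("DIMACS input has no problem line", call. = FALSE)
  weights <- rep(1, n)
  if (length(wmap) > 0L)
    weights[as.integer(names(wmap))] <- unlist(wmap, use.names = FALSE)
  em <- if (length(edges)) do.call(rbind, edges) else NULL
  weighted_graph(n, em, weights)
}

dimacs_lines <- function(x) {
  if (!is.character(x) || length(x) == 0L)
    stop("`x` must be a file path or character text", call. = FALSE)
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE)) {
    if (identical(x, "-")) return(readLines(file("stdin")))
    if (file.exists(x)) return(readLines(x, warn = FALSE))
    # a one-line DIMACS document (starts with a c/p/e/v record) is accepted
    # as text; anything else is a bad path
    if (!grepl("^[[:space:]]*[cpev]([[:space:]]|$)", x))
      stop("file not found: ", x, call. = FALSE)
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

dimacs_int <- function(tok, line) {
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v) || v %% 1 != 0)
    stop("DIMACS line ", line, ": expected an integer, got `", tok, "`",
         call. = FALSE)
  as.integer(v)
}

#' Write a graph in ASCII DIMACS clique format
#'
#' Emits `p edge n m`, one `e i j` line per edge with `i < j`, and one
#' `v i w` weight line per vertex. `read_dimacs(write_dimacs(g))` recovers
#' the vertex count, edge set and weight vector exactly.
#'
#' @param g A [weighted_graph()].
#' @param path Optional file path (or `""`/connection) to write to; when
#'   `NULL` (default) the document is returned as a character vector of lines.
#' @return The lines, invisibly when `path` is given.
#' @export
write_dimacs <- function(g, path = NULL) {
  stopifnot_graph(g)
  e <- graph_edges(g)
  lines <- c(
    sprintf("p edge %d %d", g$n, nrow(e)),
    sprintf("e %d %d", e$from, e$to),
    sprintf("v %d %s", seq_len(g$n),
            format(g$weights, scientific = FALSE, trim = TRUE))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
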