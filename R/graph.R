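#' Areal adjacency graph
#'
#' Symmetric 0/1 neighbourhood structure over areal units.  Self-edges are
#' rejected, duplicate edges (in either orientation) are collapsed, every
#' unit must have at least one neighbour and the graph must be connected
#' (a single component), as required by the ICAR prior with a single
#' per-year centering constraint.
#'
#' @param edges two-column integer matrix of unit pairs (1-based).
#' @param n_units number of units.
#' @return An object of class `adjacency_graph` with elements `n`, `edges`
#'   (deduplicated, `i < l`), `nbr` (neighbour index list) and `degrees`.
#' @export
adjacency_graph <- function(edges, n_units) {
  edges <- matrix(as.integer(edges), ncol = 2)
  n_units <- as.integer(n_units)
  if (n_units < 2L) stop("at least two units are required")
  if (any(edges < 1L | edges > n_units))
    stop("edge index out of range 1..n_units")
  if (any(edges[, 1] == edges[, 2]))
    stop("self-edges are not allowed")
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_units - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no != 1L) {
    members <- split(seq_len(n_units), comp$membership)
    stop("adjacency graph is not connected; components: ",
         paste(vapply(members, function(x) paste(x, collapse = ","), ""),
               collapse = " | "))
  }
  nbr <- lapply(seq_len(n_units), function(i)
    sort(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])))
  deg <- lengths(nbr)
  structure(list(n = n_units, edges = edges, nbr = nbr,
                 degrees = as.integer(deg)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d units, %d edges, degrees %d..%d\n",
              x$n, nrow(x$edges), min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Regular `rows x cols` grid with horizontal and vertical neighbours; a
#' synthetic stand-in for a county adjacency structure.
#'
#' @param rows,cols positive grid dimensions with `rows * cols >= 2`.
#' @return An [adjacency_graph] with `rows * cols` units.
#' @export
lattice_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L || rows * cols < 2L)
    stop("lattice must have at least 2 cells")
  id <- function(r, cc) (cc - 1L) * rows + r
  e <- list()
  for (cc in seq_len(cols)) for (r in seq_len(rows)) {
    if (r < rows) e[[length(e) + 1L]] <- c(id(r, cc), id(r + 1L, cc))
    if (cc < cols) e[[length(e) + 1L]] <- c(id(r, cc), id(r, cc + 1L))
  }
  adjacency_graph(do.call(rbind, e), rows * cols)
}

# graph Laplacian D - W (dense; graphs here are modest in size)
graph_laplacian <- function(graph) {
  L <- matrix(0, graph$n, graph$n)
  for (ei in seq_len(nrow(graph$edges))) {
    i <- graph$edges[ei, 1]; l <- graph$edges[ei, 2]
    L[i, l] <- L[i, l] - 1
    L[l, i] <- L[l, i] - 1
  }
  diag(L) <- graph$degrees
  L
}

# CSR neighbour layout for the C++ kernels (0-based)
graph_csr <- function(graph) {
  list(nbr = as.integer(unlist(graph$nbr) - 1L),
       ptr = as.integer(c(0L, cumsum(lengths(graph$nbr)))))
}
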