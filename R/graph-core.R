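#' Construct a validated evolutionary graph
#'
#' Builds a simple undirected graph on `n_nodes` nodes (indexed 1..N) from an
#' edge list. Self-loops and out-of-range endpoints are rejected; duplicate
#' edges and `(j, i)` doubles of `(i, j)` are collapsed. The result is an
#' [igraph][igraph::igraph-package] object, the representation used throughout
#' the package. Graphs are treated as immutable values: every operation that
#' "modifies" a graph (GA mutation, recombination, ...) returns a new one, so
#' fixation results can be memoized safely by canonical label.
#'
#' @param n_nodes Number of nodes N (positive integer).
#' @param edges Edges as a two-column matrix or data frame of node indices in
#'   `1..n_nodes`, or `NULL` for an edgeless graph.
#' @return An undirected simple `igraph` graph with `n_nodes` vertices.
#' @examples
#' evo_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))  # triangle K3
#' @export
evo_graph <- function(n_nodes, edges = NULL) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 1 ||
      n_nodes != round(n_nodes)) {
    stop("`n_nodes` must be a single positive integer", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    return(g)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("`edges` must have two columns", call. = FALSE)
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("`edges` contains missing values", call. = FALSE)
  if (any(edges < 1 | edges > n_nodes)) {
    stop("edge endpoint out of range 1..n_nodes", call. = FALSE)
  }
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  keep <- !duplicated(cbind(lo, hi))
  igraph::add_edges(g, rbind(lo[keep], hi[keep]))
}

#' Test whether a graph is connected
#'
#' @param g An undirected graph.
#' @return `TRUE` iff a single component covers all nodes.
#' @export
graph_is_connected <- function(g) {
  igraph::is_connected(g)
}

#' Node degrees and regularity
#'
#' `graph_degrees()` returns the degree of every node (or of a subset);
#' `is_regular()` tests whether all degrees are equal, as for the cycle or the
#' complete graph. Regular graphs are exactly the isothermal graphs of
#' evolutionary graph theory: their uniform fixation probability equals the
#' complete graph's.
#'
#' @param g An undirected graph.
#' @param nodes Node indices, default all.
#' @return Integer degrees, respectively a logical scalar.
#' @export
graph_degrees <- function(g, nodes = NULL) {
  n <- igraph::vcount(g)
  if (is.null(nodes)) nodes <- seq_len(n)
  if (any(nodes < 1 | nodes > n)) stop("node index out of range", call. = FALSE)
  as.integer(igraph::degree(g, v = nodes))
}

#' @rdname graph_degrees
#' @export
is_regular <- function(g) {
  d <- graph_degrees(g)
  length(unique(d)) <= 1
}

#' Canonical label of a graph
#'
#' Returns a string that identifies the isomorphism class of `g`: two graphs
#' receive the same label iff they are isomorphic. The label is the graph6
#' encoding of the BLISS canonical form ([igraph::canonical_permutation()]),
#' and doubles as a deterministic, lexicographically orderable key for
#' deduplication during enumeration and for the solver cache.
#'
#' @param g An undirected graph.
#' @return A single string (canonical graph6).
#' @seealso [write_graph6()]
#' @export
canonical_label <- function(g) {
  write_graph6(canonical_form(g))
}

# Canonically relabeled copy of g (deterministic across sessions).
canonical_form <- function(g) {
  igraph::permute(g, igraph::canonical_permutation(g)$labeling)
}

# --- internal bit-vector representation -------------------------------------
# Graphs of fixed size n are also handled as logical vectors over the
# column-major upper triangle (the graph6 bit order): pair k corresponds to
# (i, j), i < j, ordered by j then i. Index of (i, j): choose(j - 1, 2) + i.

pair_index <- function(n) {
  e <- cache_env("pairs")
  key <- as.character(n)
  p <- e[[key]]
  if (!is.null(p)) return(p)
  p <- if (n < 2) {
    matrix(integer(0), 0, 2)
  } else {
    do.call(rbind, lapply(2:n, function(j) cbind(seq_len(j - 1), j)))
  }
  storage.mode(p) <- "integer"
  e[[key]] <- p
  p
}

graph_from_bits <- function(bits, n, pairs = pair_index(n)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!any(bits)) return(g)
  igraph::add_edges(g, t(pairs[bits, , drop = FALSE]))
}

bits_from_graph <- function(g) {
  n <- igraph::vcount(g)
  bits <- logical(choose(n, 2))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    i <- pmin(el[, 1], el[, 2])
    j <- pmax(el[, 1], el[, 2])
    bits[choose(j - 1, 2) + i] <- TRUE
  }
  bits
}

bits_connected <- function(bits, n, pairs = pair_index(n)) {
  as.logical(connected_rows_cpp(matrix(bits, nrow = 1), pairs, n))
}
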