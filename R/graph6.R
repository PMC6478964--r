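#' graph6 encoding and decoding
#'
#' graph6 is the compact ASCII format for undirected simple graphs used by
#' nauty's `geng`/`showg` and most graph-enumeration tools: one byte `N + 63`
#' for the node count, then the upper-triangle adjacency bits in column-major
#' order (x(1,2), x(1,3), x(2,3), x(1,4), ...), packed six per byte, most
#' significant bit first, zero-padded, each byte offset by 63. Sizes up to 62
#' nodes (single-byte header) are supported, which covers everything this
#' package can solve; the multi-byte header dialects and sparse6 are not.
#'
#' @param text A single graph6 string.
#' @param g An undirected graph.
#' @return `parse_graph6()` returns an `igraph` graph; `write_graph6()` a
#'   single string. `write_graph6(parse_graph6(s))` reproduces `s` exactly,
#'   and `parse_graph6(write_graph6(g))` is identical to `g` up to the node
#'   labelling it already has.
#' @examples
#' write_graph6(evo_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3))))  # "Bw"
#' @export
parse_graph6 <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      nchar(text) == 0) {
    stop("`text` must be a single non-empty graph6 string", call. = FALSE)
  }
  bytes <- utf8ToInt(text) - 63L
  if (any(bytes < 0L | bytes > 63L)) {
    stop("invalid graph6 character", call. = FALSE)
  }
  if (bytes[1] == 63L) {
    stop("graph6 strings for more than 62 nodes are not supported",
         call. = FALSE)
  }
  n <- bytes[1]
  if (n < 1L) stop("graph6 header encodes an empty graph", call. = FALSE)
  np <- choose(n, 2)
  need <- ceiling(np / 6)
  if (length(bytes) - 1L != need) {
    stop("graph6 payload has wrong length for ", n, " nodes", call. = FALSE)
  }
  if (need == 0) return(evo_graph(n))
  bit_mat <- vapply(5:0, function(s) bitwAnd(bitwShiftR(bytes[-1], s), 1L),
                    integer(need))
  bits <- as.vector(t(matrix(bit_mat, nrow = need)))
  if (np < length(bits) && any(bits[(np + 1):length(bits)] != 0L)) {
    stop("graph6 padding bits are not zero", call. = FALSE)
  }
  graph_from_bits(as.logical(bits[seq_len(np)]), n)
}

#' @rdname parse_graph6
#' @export
write_graph6 <- function(g) {
  n <- igraph::vcount(g)
  if (n < 1) stop("graph must have at least one node", call. = FALSE)
  if (n > 62) stop("graph6 output supported up to 62 nodes", call. = FALSE)
  bits <- bits_from_graph(g)
  np <- length(bits)
  need <- ceiling(np / 6)
  out <- integer(1 + need)
  out[1] <- n + 63L
  if (need > 0) {
    padded <- c(as.integer(bits), integer(need * 6 - np))
    groups <- matrix(padded, nrow = 6)
    out[-1] <- as.integer(crossprod(groups, 2^(5:0))) + 63L
  }
  intToUtf8(out)
}

#' Read and write graph6 files
#'
#' One graph per line, interoperable with the output of `geng <n> -c`.
#'
#' @param path File path.
#' @param graphs A list of graphs (or a single graph).
#' @return `read_graph6_file()` returns a list of `igraph` graphs;
#'   `write_graph6_file()` returns `path` invisibly.
#' @export
read_graph6_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  # geng headers like ">>graph6<<" may prefix the first line
  lines[1] <- sub("^>>graph6<<", "", lines[1])
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_graph6)
}

#' @rdname read_graph6_file
#' @export
write_graph6_file <- function(graphs, path) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  writeLines(vapply(graphs, write_graph6, character(1)), path)
  invisible(path)
}

#' Read and write plain edge-list files
#'
#' Minimal text format: the first line holds N, each following non-empty line
#' one edge "i j" with 1-based node indices.
#'
#' @param path File path.
#' @param g An undirected graph.
#' @return `read_edgelist_file()` returns an `igraph` graph;
#'   `write_edgelist_file()` returns `path` invisibly.
#' @export
read_edgelist_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("first line must be the node count", call. = FALSE)
  if (length(lines) == 1) return(evo_graph(n))
  parts <- strsplit(lines[-1], "[[:space:]]+")
  edges <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  evo_graph(n, edges)
}

#' @rdname read_edgelist_file
#' @export
write_edgelist_file <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE)
  writeLines(c(as.character(igraph::vcount(g)),
               paste(el[, 1], el[, 2])), path)
  invisible(path)
}
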