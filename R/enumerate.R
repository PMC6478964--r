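#' Count unlabeled simple graphs, total and connected
#'
#' Exact counts of isomorphism classes of simple graphs on `n` nodes via the
#' cycle index of the pair action of the symmetric group (Polya enumeration),
#' and of connected graphs via the inverse Euler transform of that sequence.
#' Pure integer arithmetic (128-bit internally); no graph is ever generated,
#' which is what makes the billion-graph sizes instantaneous and provides an
#' independent cross-check of the explicit enumeration.
#'
#' @param n Number of nodes, 1 <= n <= 13 (larger counts exceed the exactly
#'   representable double range).
#' @param cumulative If `TRUE`, return one row per size 1..n.
#' @return A tibble with columns `n`, `all_graphs`, `connected_graphs`.
#' @examples
#' count_graphs(10)  # 12005168 graphs, 11716571 of them connected
#' @export
count_graphs <- function(n, cumulative = FALSE) {
  if (length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  m <- graph_counts_cpp(as.integer(n))
  out <- tibble::tibble(n = seq_len(n),
                        all_graphs = m[, "all"],
                        connected_graphs = m[, "connected"])
  if (cumulative) out else out[n, ]
}

#' Enumerate all connected unlabeled graphs of a given size
#'
#' Produces exactly one representative per isomorphism class of connected
#' simple graphs on `n` nodes, as canonical graph6 strings in lexicographic
#' order. The workhorse (`method = "extend"`) grows graphs one node at a
#' time: every connected graph on n nodes arises from a connected graph on
#' n - 1 nodes (delete any non-cut vertex) by attaching a new node to a
#' nonempty subset of the old ones, so extending all (n-1)-classes by all
#' subsets and deduplicating by canonical label is complete. The brute-force
#' method sweeps all 2^C(n,2) labeled edge sets and serves as the trusted
#' oracle for small n; both must (and do) agree, and both match
#' [count_graphs()].
#'
#' @param n Number of nodes; native cap 8 (11,117 classes) for `"extend"`,
#'   6 for `"brute"`. Larger sizes should be read from external graph6 files
#'   ([read_graph6_file()]).
#' @param method `"extend"` (default) or `"brute"`.
#' @return Character vector of canonical graph6 strings, sorted.
#' @examples
#' enumerate_connected_graphs(4)  # 6 classes
#' @export
enumerate_connected_graphs <- function(n, method = c("extend", "brute")) {
  method <- match.arg(method)
  if (length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (method == "brute") {
    if (n > 6) stop("brute-force enumeration capped at n = 6", call. = FALSE)
    return(enum_brute(n))
  }
  if (n > 8) {
    stop("native enumeration capped at n = 8; read larger sizes from a ",
         "graph6 file", call. = FALSE)
  }
  e <- cache_env("enum")
  key <- as.character(n)
  res <- e[[key]]
  if (!is.null(res)) return(res)
  if (n == 1) {
    res <- write_graph6(evo_graph(1))
  } else {
    prev <- enumerate_connected_graphs(n - 1)
    seen <- new.env(parent = emptyenv())
    subsets <- lapply(1:(2^(n - 1) - 1), function(mask) {
      which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2))) != 0L)
    })
    for (s6 in prev) {
      base <- igraph::add_vertices(parse_graph6(s6), 1)
      for (sub in subsets) {
        h <- igraph::add_edges(base, rbind(sub, n))
        lab <- canonical_label(h)
        if (is.null(seen[[lab]])) seen[[lab]] <- TRUE
      }
    }
    res <- sort(ls(seen), method = "radix")
  }
  e[[key]] <- res
  res
}

enum_brute <- function(n) {
  if (n == 1) return(write_graph6(evo_graph(1)))
  pairs <- pair_index(n)
  np <- nrow(pairs)
  masks <- 0:(2^np - 1)
  bits <- vapply(seq_len(np),
                 function(k) bitwAnd(masks, bitwShiftL(1L, k - 1L)) != 0L,
                 logical(length(masks)))
  conn <- connected_rows_cpp(bits, pairs, n)
  labs <- vapply(which(conn), function(row) {
    canonical_label(graph_from_bits(bits[row, ], n, pairs))
  }, character(1))
  sort(unique(labs), method = "radix")
}

#' Exhaustively scan the probability-time plane
#'
#' Solves fixation probability and conditional fixation time for every
#' connected graph of size `n` (one row per isomorphism class, in
#' lexicographic canonical-graph6 order), the raw material of the
#' probability-time "map". Results are memoized per (graph, r, rule), so
#' repeated scans and the genetic algorithm share work.
#'
#' @inheritParams transition_kernel
#' @param n Graph size (within the enumeration cap).
#' @param graph6 Optional character vector of graph6 strings to scan instead
#'   of the full enumeration (e.g. read from an external `geng` file).
#' @return A tibble with columns `graph6`, `phi`, `tau`.
#' @examples
#' scan5 <- exhaustive_scan(5, r = 1)
#' all.equal(unique(scan5$phi), 0.2)  # neutral: phi = 1/N on every graph
#' @export
exhaustive_scan <- function(n = NULL, r, rule = "Bd", graph6 = NULL,
                            max_nodes = 16) {
  rule <- check_rule(rule)
  if (is.null(graph6)) {
    if (is.null(n)) stop("supply `n` or `graph6`", call. = FALSE)
    graph6 <- enumerate_connected_graphs(n)
  } else {
    graph6 <- sort(vapply(graph6, function(s) canonical_label(parse_graph6(s)),
                          character(1), USE.NAMES = FALSE), method = "radix")
  }
  vals <- vapply(graph6, fixation_uniform_cached, c(phi = 0, tau = 0), r = r,
                 rule = rule, max_nodes = max_nodes, USE.NAMES = FALSE)
  tibble::tibble(graph6 = graph6, phi = vals[1, ], tau = vals[2, ])
}
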