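# Generators for the extremal graph families of the probability-time plane
# and the usual reference graphs. All seeded generators draw from R's RNG;
# passing `seed` makes them bit-reproducible.

#' Reference graphs
#'
#' The complete graph (the well-mixed baseline), the cycle (the simplest
#' regular graph), and the star (the classic undirected amplifier of
#' selection, center at node 1).
#'
#' @param n Number of nodes.
#' @return An `igraph` graph.
#' @export
complete_graph <- function(n) {
  evo_graph(n, if (n >= 2) t(utils::combn(n, 2)))
}

#' @rdname complete_graph
#' @export
cycle_graph <- function(n) {
  stopifnot(n >= 3)
  evo_graph(n, cbind(1:n, c(2:n, 1)))
}

#' @rdname complete_graph
#' @export
star_graph <- function(n) {
  stopifnot(n >= 2)
  evo_graph(n, cbind(1, 2:n))
}

#' Comet-kite graphs
#'
#' A clique of `c` nodes (the "kite"), `t` tail roots attached to clique node
#' `c` in star-like fashion, and each of the remaining `n - c - t` nodes
#' attached by a single link to a uniformly chosen current tail node
#' (including previously attached extension nodes), growing comet-like tails.
#' The edge count is always `choose(c, 2) + t + (n - c - t)`. The standard
#' kite ([standard_kite()]) is the deterministic special case whose tail is a
#' single path.
#'
#' @param n Number of nodes.
#' @param c Clique size, `1 <= c`, `c + t <= n`.
#' @param t Number of tail roots; must be positive when `n > c`.
#' @param seed Optional integer seed for reproducibility.
#' @return An `igraph` graph.
#' @examples
#' comet_kite(5, c = 4, t = 1)  # K4 plus one pendant node
#' @export
comet_kite <- function(n, c, t, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, c >= 1, t >= 0, c + t <= n)
  if (n > c + t && t == 0) {
    stop("tail extensions require at least one tail root (t >= 1)",
         call. = FALSE)
  }
  edges <- if (c >= 2) t(utils::combn(c, 2)) else NULL
  if (t > 0) edges <- rbind(edges, cbind(c, c + seq_len(t)))
  tails <- c + seq_len(t)
  for (v in seq_len(n - c - t) + c + t) {
    edges <- rbind(edges, c(sample(tails, 1), v))
    tails <- c(tails, v)
  }
  evo_graph(n, edges)
}

#' @rdname comet_kite
#' @export
standard_kite <- function(n, c) {
  stopifnot(c >= 1, c <= n)
  edges <- if (c >= 2) t(utils::combn(c, 2)) else NULL
  if (n > c) edges <- rbind(edges, cbind(c:(n - 1), (c + 1):n))
  evo_graph(n, edges)
}

#' Detour graphs
#'
#' The strongest suppressors of selection among small undirected graphs share
#' a common shape: a densely connected "core" bridged by a sparse "detour".
#' `detour_graph()` samples one at random: a clique core of size `c`; an
#' outer region of `o` nodes, `o` drawn uniformly from `2 .. min(c, n-c-1)`,
#' each outer node joined to a random nonempty subset of the core; and a
#' detour built by adding links from the remaining `n - c - o` nodes randomly
#' to the outer region or to other detour nodes until every detour node has
#' at least two connections. If the outer region fails to connect with the
#' detour, the detour wiring is redrawn (keeping `n`, `c`, `o`) up to
#' `max_tries` times.
#'
#' `standard_detour()` is the deterministic variant with `o = 2` where the
#' detour is a path connecting one outer node to the other in a ring-like
#' fashion; the two outer nodes are joined to the two halves of the core
#' (ceiling/floor split). With `c = n - 2` the detour shrinks to a single
#' link between two nodes each connected to half the core — exactly the
#' l-graph, see [l_graph()].
#'
#' @param n Number of nodes.
#' @param c Core clique size; `2 <= c <= n - 4` for the random variant,
#'   `2 <= c <= n - 2` for the standard one.
#' @param seed Optional integer seed.
#' @param max_tries Retry budget for the detour wiring.
#' @return An `igraph` graph. The node layout is core `1..c`, outer region
#'   next, detour nodes last; `detour_graph()` records the sampled partition
#'   in the graph attributes `core_size` and `outer_size`.
#' @export
detour_graph <- function(n, c, seed = NULL, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(c >= 2, c <= n - 4)
  o_max <- min(c, n - c - 1)
  o <- if (o_max == 2) 2L else sample(2:o_max, 1)
  core <- seq_len(c)
  outer <- c + seq_len(o)
  det <- setdiff(seq_len(n), c(core, outer))
  base <- t(utils::combn(c, 2))
  for (v in outer) {
    sub <- which(runif(c) < 0.5)
    if (length(sub) == 0) sub <- sample(core, 1)
    base <- rbind(base, cbind(sub, v))
  }
  for (try in seq_len(max_tries)) {
    edges <- base
    repeat {
      g <- evo_graph(n, edges)
      degs <- graph_degrees(g, det)
      low <- det[degs < 2]
      if (length(low) == 0) break
      u <- low[1]
      cand <- setdiff(c(outer, det), u)
      cand <- cand[!cand %in% igraph::neighbors(g, u)]
      if (length(cand) == 0) break  # dead end, retry wiring
      edges <- rbind(edges, c(u, cand[sample.int(length(cand), 1)]))
    }
    g <- evo_graph(n, edges)
    ok <- all(graph_degrees(g, det) >= 2) &&
      graph_is_connected(g) &&
      all(vapply(outer, function(v) {
        any(as.integer(igraph::neighbors(g, v)) %in% det)
      }, logical(1)))
    if (ok) {
      g <- igraph::set_graph_attr(g, "core_size", c)
      g <- igraph::set_graph_attr(g, "outer_size", o)
      return(g)
    }
  }
  stop("failed to wire a valid detour in ", max_tries, " attempts",
       call. = FALSE)
}

#' @rdname detour_graph
#' @export
standard_detour <- function(n, c) {
  stopifnot(c >= 2, c <= n - 2)
  u <- c + 1L
  v <- c + 2L
  half <- ceiling(c / 2)
  edges <- rbind(t(utils::combn(c, 2)),
                 cbind(seq_len(half), u),
                 cbind(seq(half + 1, c), v))
  det <- setdiff(seq_len(n), seq_len(c + 2))
  path <- c(u, det, v)
  edges <- rbind(edges, cbind(path[-length(path)], path[-1]))
  evo_graph(n, edges)
}

#' l-graphs
#'
#' A clique core of size `n - 2` plus two extra nodes joined to each other
#' and each joined to (as near as possible) half of the core. These graphs
#' are true suppressors of selection for every fitness r at small sizes:
#' advantageous mutants fix with lower, disadvantageous mutants with higher
#' probability than on the complete graph. Structurally the degenerate
#' standard detour whose detour is a single link.
#'
#' @param n Number of nodes, `n >= 4`.
#' @return An `igraph` graph.
#' @export
l_graph <- function(n) {
  stopifnot(n >= 4)
  standard_detour(n, n - 2)
}

#' Generalized star graphs
#'
#' Complete bipartite graph with `a` hub nodes and `n - a` leaves, plus
#' Bernoulli(`p`) links inside the hub partition. `a = 1` gives the ordinary
#' star for any `p`; `p = 0` the complete bipartite graph; `p = 1` a clique
#' hub. These graphs populate the high-fixation-probability edge of the
#' probability-time plane.
#'
#' @param n Number of nodes.
#' @param a Hub partition size, `1 <= a <= n/2`.
#' @param p Intra-hub connection probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An `igraph` graph (hub nodes are `1..a`).
#' @export
generalized_star <- function(n, a, p = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(a >= 1, a <= n / 2, p >= 0, p <= 1)
  edges <- as.matrix(expand.grid(seq_len(a), a + seq_len(n - a)))
  if (a >= 2 && p > 0) {
    hub <- t(utils::combn(a, 2))
    edges <- rbind(edges, hub[runif(nrow(hub)) < p, , drop = FALSE])
  }
  evo_graph(n, edges)
}

#' Coupled star graphs
#'
#' Two star centers joined by a link; `a` leaves on the first center and
#' `n - a - 2` on the second. Always a tree (n - 1 edges) with center degrees
#' `a + 1` and `n - a - 1`. Coupled stars are the slowest-fixating graphs at
#' moderate sizes: nearly the fixation probability of a generalized star with
#' two centers, but far longer conditional fixation times.
#'
#' @param n Number of nodes.
#' @param a Leaves on the first center, `0 <= a <= n - 2`.
#' @return An `igraph` graph (centers are nodes 1 and 2).
#' @export
coupled_star <- function(n, a) {
  stopifnot(n >= 2, a >= 0, a <= n - 2)
  edges <- rbind(c(1, 2),
                 if (a > 0) cbind(1, 2 + seq_len(a)),
                 if (n - a - 2 > 0) cbind(2, 2 + a + seq_len(n - a - 2)))
  evo_graph(n, edges)
}

#' Connected Erdos-Renyi graph
#'
#' Every potential link is present independently with probability `p_link`;
#' the draw is repeated until the result is connected. This is the
#' initialization distribution of the genetic algorithm.
#'
#' @param n Number of nodes.
#' @param p_link Link probability.
#' @param seed Optional integer seed.
#' @param max_tries Resampling budget.
#' @return A connected `igraph` graph.
#' @export
erdos_renyi_connected <- function(n, p_link = 0.5, seed = NULL,
                                  max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, p_link >= 0, p_link <= 1)
  pairs <- pair_index(n)
  np <- nrow(pairs)
  for (i in seq_len(max_tries)) {
    bits <- runif(np) < p_link
    if (n == 1 || bits_connected(bits, n, pairs)) {
      return(graph_from_bits(bits, n, pairs))
    }
  }
  stop("failed to draw a connected graph in ", max_tries, " attempts",
       call. = FALSE)
}
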