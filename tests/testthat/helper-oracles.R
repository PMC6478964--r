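# Independent oracles used across the suite.

# all permutations of 1..n (n <= 7), as a list
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(all_perms(n - 1), function(p) {
    lapply(seq_len(n), function(pos) append(p, n, after = pos - 1))
  }))
}

# brute-force isomorphism by trying every relabeling of g1
brute_isomorphic <- function(g1, g2) {
  n <- igraph::vcount(g1)
  if (igraph::vcount(g2) != n) return(FALSE)
  if (igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  a2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  a1 <- igraph::as_adjacency_matrix(g1, sparse = FALSE)
  for (p in all_perms(n)) {
    if (all(a1[p, p] == a2)) return(TRUE)
  }
  FALSE
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

random_connected <- function(n, seed, p = 0.5) {
  erdos_renyi_connected(n, p, seed = seed)
}
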