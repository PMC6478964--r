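test_that("comet-kite structure: clique, tails, and exact edge count", {
  g <- comet_kite(5, c = 4, t = 1)  # standard kite: K4 plus pendant
  expect_true(graph_is_connected(g))
  expect_equal(igraph::ecount(g), choose(4, 2) + 1)
  expect_equal(sort(graph_degrees(g)), c(1L, 3L, 3L, 3L, 4L))

  expect_identical(canonical_label(comet_kite(4, c = 4, t = 0)),
                   canonical_label(complete_graph(4)))  # degenerate case

  for (s in 1:10) {
    g <- comet_kite(9, c = 4, t = 2, seed = s)
    expect_true(graph_is_connected(g))
    expect_equal(igraph::ecount(g), choose(4, 2) + 2 + (9 - 4 - 2))
  }
  expect_error(comet_kite(6, c = 3, t = 0), "tail root")
  expect_error(comet_kite(5, c = 4, t = 2), "c \\+ t")

  pathy <- standard_kite(7, c = 4)
  expect_equal(igraph::ecount(pathy), choose(4, 2) + 3)
  expect_equal(max(graph_degrees(pathy)), 4)
})

test_that("random detours obey the degree and attachment contract", {
  for (s in 1:25) {
    g <- detour_graph(10, c = 4, seed = s)
    expect_true(graph_is_connected(g))
    core <- 1:4
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_true(all(A[core, core][upper.tri(diag(4))] == 1))  # clique core
    o <- igraph::graph_attr(g, "outer_size")
    expect_true(o >= 2 && o <= min(4, 10 - 4 - 1))
    outer <- 4 + seq_len(o)
    det <- setdiff(1:10, c(core, outer))
    # every detour node has at least two connections
    expect_true(all(graph_degrees(g, det) >= 2))
    # the outer region connects with the detour
    expect_true(all(rowSums(A[outer, det, drop = FALSE]) >= 1))
  }
  expect_error(detour_graph(6, c = 4), "c <= n - 4")
})

test_that("standard detour and l-graph have the documented shape", {
  g <- standard_detour(8, c = 4)
  expect_true(graph_is_connected(g))
  # two outer nodes joined to half the core each; 2-node path detour
  expect_equal(graph_degrees(g, 5:8), c(3L, 3L, 2L, 2L))

  lg <- l_graph(10)
  expect_identical(canonical_label(lg),
                   canonical_label(standard_detour(10, 8)))
  # clique core of 8, two bridge nodes of degree ceil/floor(8/2) + 1
  expect_equal(sort(graph_degrees(lg, 9:10)), c(5L, 5L))
  expect_equal(igraph::ecount(lg), choose(8, 2) + 8 + 1)
  expect_error(l_graph(3), "n >= 4")
})

test_that("generalized stars interpolate between bipartite and clique hubs", {
  expect_identical(canonical_label(generalized_star(8, a = 1, p = 0.7, seed = 1)),
                   canonical_label(star_graph(8)))
  expect_equal(igraph::ecount(generalized_star(9, a = 3, p = 0)), 3 * 6)
  expect_equal(igraph::ecount(generalized_star(9, a = 3, p = 1)),
               3 * 6 + choose(3, 2))
  expect_error(generalized_star(8, a = 5, p = 0), "a <= n/2")
})

test_that("coupled stars are trees with the prescribed center degrees", {
  g <- coupled_star(10, 4)
  expect_equal(igraph::ecount(g), 9)
  expect_equal(graph_degrees(g, 1:2), c(5L, 5L))
  expect_true(graph_is_connected(g))

  g0 <- coupled_star(6, 0)
  expect_equal(igraph::ecount(g0), 5)
  expect_equal(sort(graph_degrees(g0, 1:2)), c(1L, 5L))
  expect_error(coupled_star(6, 5), "a <= n - 2")
})

test_that("seeded generators are reproducible and always valid", {
  gens <- list(
    function(s) comet_kite(9, 5, 2, seed = s),
    function(s) detour_graph(9, 3, seed = s),
    function(s) generalized_star(9, 4, 0.5, seed = s),
    function(s) erdos_renyi_connected(9, 0.4, seed = s)
  )
  for (gen in gens) {
    expect_identical(edge_set(gen(42)), edge_set(gen(42)))
    g <- gen(7)
    expect_true(graph_is_connected(g))
    expect_equal(sum(graph_degrees(g)), 2 * igraph::ecount(g))
  }
})
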