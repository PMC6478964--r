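test_that("transition kernel matches hand-computed probabilities on K2", {
  k2 <- evo_graph(2, cbind(1, 2))
  kern <- transition_kernel(k2, r = 2, rule = "Bd")
  # state {1} (bitmask 1, row 2): total fitness 2 + 1 = 3
  expect_equal(kern$gain[2, 2], 2 / 3)
  expect_equal(kern$loss[2, 1], 1 / 3)
  # absorbing states have all-zero rows
  expect_true(all(kern$gain[1, ] == 0) && all(kern$loss[1, ] == 0))
  expect_true(all(kern$gain[4, ] == 0) && all(kern$loss[4, ] == 0))

  # dB on K2 is neutral regardless of r: the dying node is replaced by the
  # only other individual
  dk <- transition_kernel(k2, r = 5, rule = "dB")
  expect_equal(dk$gain[2, 2], 1 / 2)
  expect_equal(dk$loss[2, 1], 1 / 2)
})

test_that("kernel probabilities are well formed on every 4-node graph", {
  for (rule in c("Bd", "dB")) {
    for (s6 in enumerate_connected_graphs(4)) {
      kern <- transition_kernel(parse_graph6(s6), r = 1.7, rule = rule)
      expect_true(all(kern$gain >= 0) && all(kern$loss >= 0))
      expect_true(all(rowSums(kern$gain) + rowSums(kern$loss) <= 1 + 1e-12))
      # gains only across edges into non-mutant nodes: recompute one state
      A <- igraph::as_adjacency_matrix(parse_graph6(s6), sparse = FALSE)
      no_edge_to_1 <- which(A[, 1] == 0)
      no_edge_to_1 <- setdiff(no_edge_to_1, 1)
      for (j in no_edge_to_1) {
        expect_equal(kern$gain[1 + 2^(j - 1), 1], 0)
      }
    }
  }
  expect_error(transition_kernel(evo_graph(4, rbind(c(1, 2), c(3, 4))), 1),
               "connected")
})

test_that("well-mixed closed form and solver agree on complete graphs", {
  expect_equal(moran_complete(4, 2), 8 / 15)
  expect_equal(moran_complete(7, 1), 1 / 7)
  expect_equal(moran_complete(1000, 2), 1 / 2, tolerance = 1e-9)
  expect_error(moran_complete(1, 2), ">= 2")
  expect_error(moran_complete(4, -1), "positive")

  for (n in c(3, 5)) {
    for (r in c(0.6, 1.25, 2)) {
      expect_equal(fixation(complete_graph(n), r)$phi_uniform,
                   moran_complete(n, r), tolerance = 1e-10)
    }
  }
})

test_that("neutral mutants fix with probability 1/N, per node prop. 1/degree", {
  for (s6 in enumerate_connected_graphs(5)) {
    fx <- fixation(parse_graph6(s6), r = 1)
    expect_equal(fx$phi_uniform, 1 / 5, tolerance = 1e-10)
    d <- graph_degrees(parse_graph6(s6))
    expect_equal(fx$phi, (1 / d) / sum(1 / d), tolerance = 1e-10)
  }
})

test_that("regular graphs are isothermal", {
  regs <- list(cycle_graph(6), cycle_graph(8), complete_graph(6),
               # 3-regular prism and Moebius-Kantor-like 8-cycle with chords
               evo_graph(6, rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6),
                                  c(6, 4), c(1, 4), c(2, 5), c(3, 6))))
  for (g in regs) {
    for (r in c(0.5, 1.25, 2)) {
      expect_equal(fixation(g, r)$phi_uniform,
                   moran_complete(igraph::vcount(g), r), tolerance = 1e-10)
    }
  }
})

test_that("fixation probability increases with fitness", {
  grid <- c(0.5, 1, 1.5, 2)
  for (s in 1:5) {
    g <- random_connected(6, seed = s)
    phis <- vapply(grid, function(r) fixation(g, r)$phi_uniform, numeric(1))
    expect_true(all(diff(phis) > 0))
  }
})

test_that("conditional times respect the N-1 step floor and match Monte Carlo", {
  for (s6 in enumerate_connected_graphs(4)) {
    fx <- fixation(parse_graph6(s6), r = 1.25)
    expect_true(all(fx$tau >= 3))
  }

  k3 <- complete_graph(3)
  fx <- fixation(k3, r = 1.25)
  sim <- simulate_moran(k3, r = 1.25, n_reps = 1e5, seed = 11)
  expect_lt(abs(sim$phi_hat - fx$phi_uniform), 3 * sim$phi_se)
  expect_lt(abs(sim$tau_hat - fx$tau_uniform), 3 * sim$tau_se)

  # dB oracle check on the star, where the rules differ strongly
  st <- star_graph(5)
  fd <- fixation(st, r = 1.25, rule = "dB")
  sd <- simulate_moran(st, r = 1.25, rule = "dB", n_reps = 1e5, seed = 12)
  expect_lt(abs(sd$phi_hat - fd$phi_uniform), 3 * sd$phi_se)
  expect_lt(abs(sd$tau_hat - fd$tau_uniform), 3 * sd$tau_se)
})

test_that("simulation is reproducible and solver output is well formed", {
  g <- star_graph(5)
  a <- simulate_moran(g, 1.25, n_reps = 2000, seed = 7)
  b <- simulate_moran(g, 1.25, n_reps = 2000, seed = 7)
  expect_identical(a, b)

  fx <- fixation(g, 1.25)
  expect_true(all(fx$phi >= 0 & fx$phi <= 1))
  expect_equal(fx$phi_uniform, mean(fx$phi))
  expect_equal(fx$tau_uniform, sum(fx$phi * fx$tau) / sum(fx$phi))
  td <- tidy(fx)
  expect_equal(nrow(td), 5)
  gl <- glance(fx)
  expect_identical(gl$graph6, write_graph6(g))
})

test_that("sparse and dense linear solvers agree", {
  # force the sparse path by lifting the dense cutoff artificially: N = 12
  # exceeds the 2048-state dense cap, N = 8 uses the dense route
  g <- generalized_star(12, a = 3, p = 0, seed = 1)
  fx <- fixation(g, 1.25)  # 4094 transient states, sparse
  sub <- generalized_star(8, a = 2, p = 0, seed = 1)
  fx8 <- fixation(sub, 1.25)
  sim <- simulate_moran(g, 1.25, n_reps = 2e4, seed = 9)
  expect_lt(abs(sim$phi_hat - fx$phi_uniform), 3.5 * sim$phi_se)
  expect_true(fx8$phi_uniform > 0 && fx8$phi_uniform < 1)
})
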