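test_that("recombination keeps offspring between parental edge sets", {
  set.seed(1)
  g <- random_connected(6, seed = 3)
  expect_identical(edge_set(recombine(g, g)), edge_set(g))

  # parents differing in one link: offspring is one parent or the other
  kn <- complete_graph(5)
  km <- evo_graph(5, t(utils::combn(5, 2))[-1, ])
  for (i in 1:20) {
    child <- recombine(kn, km)
    expect_true(igraph::ecount(child) %in% c(9, 10))
  }

  for (s in 1:50) {
    set.seed(100 + s)
    a <- random_connected(7, seed = 2 * s)
    b <- random_connected(7, seed = 2 * s + 1)
    set.seed(1000 + s)
    child <- recombine(a, b)
    expect_true(graph_is_connected(child))
    ec <- edge_set(child)
    expect_true(all(intersect(edge_set(a), edge_set(b)) %in% ec))
    expect_true(all(ec %in% union(edge_set(a), edge_set(b))))
  }
  expect_error(recombine(complete_graph(4), complete_graph(5)),
               "same number of nodes")
})

test_that("mutation toggles a binomial number of links and stays connected", {
  g <- random_connected(7, seed = 5)
  expect_identical(edge_set(mutate_graph(g, 0)), edge_set(g))
  expect_error(mutate_graph(g, 100), "choose")

  # mean toggles equals b (conditioning on connectivity barely shifts it)
  set.seed(42)
  base <- complete_graph(7)  # connectivity constraint almost never binds
  b <- 1.5
  toggles <- replicate(4000, {
    child <- mutate_graph(base, b)
    length(setdiff(union(edge_set(child), edge_set(base)),
                   intersect(edge_set(child), edge_set(base))))
  })
  # binomial(21, b/21): se of the mean over 4000 reps ~ 0.019
  expect_lt(abs(mean(toggles) - b), 4 * sqrt(b * (1 - b / 21) / 4000))
  expect_true(all(vapply(1:30, function(i) {
    graph_is_connected(mutate_graph(random_connected(6, seed = i), 2))
  }, logical(1))))
})

test_that("the genetic algorithm finds known optima on small graphs", {
  cfg <- ga_config(5, r = 1.25, objective = "fixation_probability",
                   direction = "max", m = 20, k = 4, n_iter = 60, seed = 1)
  run <- run_ga(cfg)
  expect_identical(run$best_graph6, canonical_label(star_graph(5)))

  cfg2 <- ga_config(5, r = 1.25, objective = "fixation_time",
                    direction = "min", m = 20, k = 4, n_iter = 60, seed = 2)
  expect_identical(run_ga(cfg2)$best_graph6,
                   canonical_label(complete_graph(5)))
})

test_that("GA runs are deterministic, monotone, and cache isomorphs", {
  cfg <- ga_config(5, r = 1.25, objective = "fixation_probability",
                   direction = "min", m = 12, k = 3, n_iter = 40, seed = 9)
  a <- run_ga(cfg)
  b <- run_ga(cfg)
  expect_identical(a$best_graph6, b$best_graph6)
  expect_identical(a$trace, b$trace)

  # best-in-pool trace is weakly monotone in the optimizing direction
  expect_true(all(diff(a$trace$best_score) <= 1e-14))
  # never more solver calls than isomorphism classes of size 5
  expect_lte(a$evaluations, 21)

  gl <- glance(a)
  expect_identical(gl$best_graph6, a$best_graph6)
  expect_equal(nrow(tidy(a)), 40)
})

test_that("GA configuration is validated", {
  expect_error(ga_config(6, r = 1.25, k = 50, m = 40), "k <= m")
  expect_error(ga_config(6, r = -1), "r > 0")
  expect_error(ga_config(6, r = 1, b = 100), "b <= choose")
})
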