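test_that("node temperatures sum to N and detect heterogeneity", {
  tp <- temperature_profile(star_graph(5))
  expect_equal(tp$temperature, c(4, 0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(tp$temperature), 5)
  expect_equal(tp$heterogeneity, mean((tp$temperature - 1)^2))

  expect_equal(temperature_profile(cycle_graph(9))$heterogeneity, 0)
  expect_equal(temperature_profile(complete_graph(7))$heterogeneity, 0)

  for (s in 1:20) {
    g <- random_connected(8, seed = s)
    expect_equal(sum(temperature_profile(g)$temperature), 8,
                 tolerance = 1e-12)
  }
  expect_equal(nrow(tidy(temperature_profile(star_graph(4)))), 4)
})

test_that("heterogeneity correlates with fixation probability at size 6", {
  g6 <- enumerate_connected_graphs(6)
  rho <- heterogeneity_correlation(g6, r = 1.25)
  expect_gt(rho, 0)

  # permutation invariance of the input list
  rho2 <- heterogeneity_correlation(rev(g6), r = 1.25)
  expect_equal(rho, rho2)

  expect_error(heterogeneity_correlation(
    list(cycle_graph(6), cycle_graph(7), complete_graph(5)), r = 1.25),
    "zero variance")
  expect_error(heterogeneity_correlation(list(cycle_graph(5)), r = 1.25),
               "at least 3")
})

test_that("classification verdicts match known graph families", {
  expect_identical(classify_graph(cycle_graph(8))$verdict, "isothermal")
  expect_identical(classify_graph(complete_graph(7))$verdict, "isothermal")
  expect_identical(classify_graph(star_graph(6))$verdict, "amplifier")
  expect_identical(classify_graph(l_graph(8))$verdict, "suppressor")

  cl <- classify_graph(star_graph(6))
  td <- tidy(cl)
  expect_equal(td$delta, td$phi - td$phi_complete)
  expect_true(all(td$delta[td$r > 1] > 0) && all(td$delta[td$r < 1] < 0))
  expect_error(classify_graph(star_graph(5), r_grid = numeric(0)), "empty")

  # verdict is a property of the isomorphism class, not the labelling
  perm <- igraph::permute(star_graph(6), c(3, 1, 2, 6, 5, 4))
  expect_identical(classify_graph(perm)$verdict, "amplifier")
})

test_that("the probability-time plane carries tags, flags and references", {
  pl <- build_plane(6, r = 1.25, seed = 4)
  expect_equal(nrow(pl), 112)
  expect_true(all(pl$phi > 0 & pl$phi < 1))
  expect_true(all(pl$tau >= 5))
  expect_identical(pl$graph6[which.max(pl$phi)],
                   canonical_label(star_graph(6)))
  expect_identical(pl$graph6[which.min(pl$tau)],
                   canonical_label(complete_graph(6)))

  # the star is tagged as a generalized star, K6 as neither family
  expect_identical(pl$category[pl$graph6 == canonical_label(star_graph(6))],
                   "generalized_star")
  expect_identical(pl$category[pl$graph6 == canonical_label(coupled_star(6, 2))],
                   "coupled_star")
  expect_true(all(c("detour", "comet_kite") %in% pl$category))
  expect_identical(pl$has_pendant,
                   vapply(pl$graph6,
                          function(s) any(graph_degrees(parse_graph6(s)) == 1),
                          logical(1), USE.NAMES = FALSE))

  expect_equal(attr(pl, "phi_complete"), moran_complete(6, 1.25))
  p <- autoplot(pl)
  expect_s3_class(p, "ggplot")
})
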