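# Classification of graphs relative to the complete graph, node temperatures,
# and assembly of the probability-time plane.

# uniform phi of the reference complete graph (closed form under Bd, exact
# solve under dB), cached
reference_phi <- function(n, r, rule, max_nodes = 16) {
  if (rule == "Bd") return(moran_complete(n, r))
  e <- cache_env("refdb")
  key <- paste(n, r, sep = "|")
  v <- e[[key]]
  if (is.null(v)) {
    v <- fixation(complete_graph(n), r, rule = "dB",
                  max_nodes = max_nodes)$phi_uniform
    e[[key]] <- v
  }
  v
}

#' Classify a graph as amplifier, suppressor, or piecewise suppressor
#'
#' Compares the exact uniform fixation probability of `g` with the complete
#' graph of the same size over a grid of fitness values and maps the sign
#' pattern of the difference `delta(r) = phi_g(r) - phi_complete(r)` to a
#' verdict: an amplifier raises the fixation probability of advantageous
#' mutants (r > 1) and lowers it for disadvantageous ones (r < 1); a
#' suppressor is the reverse; regular graphs are isothermal (delta = 0
#' everywhere); a piecewise verdict means delta changes sign within r > 1,
#' as the detour graphs do. For piecewise graphs the sign change is bracketed
#' on the grid and refined by bisection with the exact solver.
#'
#' @inheritParams transition_kernel
#' @param r_grid Ordered positive fitness values; include points on both
#'   sides of 1 for full verdicts.
#' @param tolerance Values of `|delta|` below this count as zero.
#' @param crossing_tol Width to which a piecewise crossing is bisected.
#' @return An object of class `evo_class` with fields `graph6`, `verdict`,
#'   `r_grid`, `phi`, `phi_complete`, `delta`, and `crossing_r` (a length-2
#'   bracket, or `NULL`). See [tidy.evo_class()].
#' @examples
#' classify_graph(cycle_graph(6))$verdict  # "isothermal"
#' @export
classify_graph <- function(g, r_grid = c(0.5, 0.75, 1.25, 1.5, 1.75, 2),
                           rule = "Bd", tolerance = 1e-9,
                           crossing_tol = 1e-3, max_nodes = 16) {
  rule <- check_rule(rule)
  if (length(r_grid) == 0) stop("`r_grid` is empty", call. = FALSE)
  if (any(r_grid <= 0)) stop("`r_grid` must be positive", call. = FALSE)
  r_grid <- sort(unique(r_grid))
  n <- igraph::vcount(g)
  g6 <- canonical_label(g)
  phi <- vapply(r_grid, function(r) {
    fixation_uniform_cached(g6, r, rule, max_nodes = max_nodes)[["phi"]]
  }, numeric(1))
  ref <- vapply(r_grid, reference_phi, numeric(1), n = n, rule = rule,
                max_nodes = max_nodes)
  delta <- phi - ref
  sig <- ifelse(delta > tolerance, 1L, ifelse(delta < -tolerance, -1L, 0L))
  up <- sig[r_grid > 1]
  down <- sig[r_grid < 1]

  crossing <- NULL
  verdict <- if (all(sig == 0L)) {
    "isothermal"
  } else if (any(up == 1L) && any(up == -1L)) {
    "piecewise"
  } else if (all(up == 1L) && all(down == -1L)) {
    "amplifier"
  } else if (all(up == -1L) && all(down == 1L)) {
    "suppressor"
  } else {
    "mixed"
  }
  if (verdict == "piecewise") {
    ru <- r_grid[r_grid > 1]
    su <- up
    flip <- which(su[-1] * su[-length(su)] < 0)[1]
    lo <- ru[flip]
    hi <- ru[flip + 1]
    dlo <- delta[match(lo, r_grid)]
    while (hi - lo > crossing_tol) {
      mid <- (lo + hi) / 2
      dm <- fixation_uniform_cached(g6, mid, rule,
                                    max_nodes = max_nodes)[["phi"]] -
        reference_phi(n, mid, rule, max_nodes = max_nodes)
      if (sign(dm) == sign(dlo)) {
        lo <- mid
        dlo <- dm
      } else {
        hi <- mid
      }
    }
    crossing <- c(lo, hi)
  }
  structure(list(graph6 = g6, n = n, rule = rule, verdict = verdict,
                 r_grid = r_grid, phi = phi, phi_complete = ref,
                 delta = delta, crossing_r = crossing,
                 tolerance = tolerance),
            class = "evo_class")
}

#' @export
print.evo_class <- function(x, ...) {
  cat("Graph ", x$graph6, " (N = ", x$n, ", ", x$rule, "): ", x$verdict,
      "\n", sep = "")
  if (!is.null(x$crossing_r)) {
    cat("suppression switches to amplification in r = (",
        format(x$crossing_r[1]), ", ", format(x$crossing_r[2]), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Node temperatures and graph heterogeneity
#'
#' The temperature of node j under Bd updating is the rate at which it is
#' replaced, `T_j = sum over neighbors i of 1/deg(i)` (up to the constant
#' 1/N). Temperatures always sum to N. The heterogeneity of a graph is the
#' population variance of its node temperatures; it is zero exactly for
#' regular graphs and strongly correlated with fixation probability across
#' graphs of a given size.
#'
#' @param g A connected undirected graph.
#' @return An object of class `evo_temperature`: list with `temperature`
#'   (length-N vector) and `heterogeneity` (variance, denominator N).
#' @examples
#' temperature_profile(star_graph(5))$temperature  # center 4, leaves 1/4
#' @export
temperature_profile <- function(g) {
  if (!graph_is_connected(g)) stop("graph must be connected", call. = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(A)
  temp <- as.vector(t(A) %*% (1 / deg))
  het <- mean((temp - mean(temp))^2)
  structure(list(temperature = temp, heterogeneity = het,
                 n = igraph::vcount(g)),
            class = "evo_temperature")
}

#' @export
print.evo_temperature <- function(x, ...) {
  cat("Node temperatures (sum = N =", x$n, ")\n")
  print(x$temperature)
  cat("heterogeneity (population variance):", format(x$heterogeneity), "\n")
  invisible(x)
}

#' Correlation between heterogeneity and fixation probability
#'
#' Pearson correlation, across a set of graphs, between the temperature
#' heterogeneity and the exact uniform fixation probability at fitness `r`.
#' Positive values mean that hotter-colder contrast in replacement rates
#' goes with amplification of selection.
#'
#' @inheritParams transition_kernel
#' @param graphs A list of graphs, or a character vector of graph6 strings.
#' @return A single correlation coefficient.
#' @export
heterogeneity_correlation <- function(graphs, r, rule = "Bd",
                                      max_nodes = 16) {
  rule <- check_rule(rule)
  if (is.character(graphs)) graphs <- lapply(graphs, parse_graph6)
  if (length(graphs) < 3) stop("need at least 3 graphs", call. = FALSE)
  het <- purrr::map_dbl(graphs, ~ temperature_profile(.x)$heterogeneity)
  phi <- purrr::map_dbl(graphs, function(g) {
    fixation_uniform_cached(canonical_label(g), r, rule,
                            max_nodes = max_nodes)[["phi"]]
  })
  if (var(het) == 0 || var(phi) == 0) {
    stop("zero variance in heterogeneity or fixation probability",
         call. = FALSE)
  }
  cor(het, phi)
}

#' Assemble the probability-time plane
#'
#' Scans every connected graph of size `n` (or a supplied list), tags the
#' members of the extremal families by construction (coupled stars,
#' generalized stars, detours, comet-kites), and flags graphs with a pendant
#' (degree-1) node. The result is the "map" in which the complete graph sits
#' at minimal time, stars at maximal probability, and comet-kites and detour
#' graphs trace the low-probability border.
#'
#' @inheritParams transition_kernel
#' @param n Graph size (within the enumeration cap of 8), or `NULL` when
#'   `graph6` is given.
#' @param graph6 Optional character vector of graph6 strings to use instead
#'   of the exhaustive enumeration.
#' @param categories If `FALSE`, skip category tagging.
#' @param detour_samples Random detour draws per core size used for tagging.
#' @param p_grid Intra-hub probabilities swept for generalized stars.
#' @param seed Seed for the randomized category sweeps.
#' @return A tibble of class `evo_plane` with columns `graph6`, `phi`, `tau`,
#'   `category`, `has_pendant`, and attributes `n`, `r`, `rule`,
#'   `phi_complete`, `tau_complete`. See [autoplot.evo_plane()].
#' @export
build_plane <- function(n = NULL, r, rule = "Bd", graph6 = NULL,
                        categories = TRUE, detour_samples = 5,
                        p_grid = c(0, seq(0.1, 1, by = 0.1)), seed = 1,
                        max_nodes = 16) {
  rule <- check_rule(rule)
  scan <- exhaustive_scan(n = n, r = r, rule = rule, graph6 = graph6,
                          max_nodes = max_nodes)
  if (is.null(n)) n <- igraph::vcount(parse_graph6(scan$graph6[1]))
  tags <- if (categories) category_tags(n, detour_samples, p_grid, seed)
  category <- rep("other", nrow(scan))
  if (!is.null(tags)) {
    hit <- match(scan$graph6, tags$graph6)
    category[!is.na(hit)] <- tags$category[hit[!is.na(hit)]]
  }
  has_pendant <- vapply(scan$graph6, function(s) {
    any(graph_degrees(parse_graph6(s)) == 1L)
  }, logical(1), USE.NAMES = FALSE)
  out <- tibble::tibble(graph6 = scan$graph6, phi = scan$phi, tau = scan$tau,
                        category = category, has_pendant = has_pendant)
  kn <- canonical_label(complete_graph(n))
  ref <- fixation_uniform_cached(kn, r, rule, max_nodes = max_nodes)
  structure(out, n = n, r = r, rule = rule,
            phi_complete = ref[["phi"]], tau_complete = ref[["tau"]],
            class = c("evo_plane", class(out)))
}

# canonical labels of the category sweeps at size n, first match wins in the
# priority order coupled star > generalized star > detour > comet-kite
category_tags <- function(n, detour_samples, p_grid, seed) {
  rows <- list()
  add <- function(g, cat) {
    rows[[length(rows) + 1]] <<- c(canonical_label(g), cat)
  }
  for (a in 0:floor((n - 2) / 2)) add(coupled_star(n, a), "coupled_star")
  for (a in seq_len(floor(n / 2))) {
    for (p in p_grid) {
      add(generalized_star(n, a, p, seed = seed + round(1000 * p) + a),
          "generalized_star")
    }
  }
  if (n >= 6) {
    for (cc in 2:(n - 4)) {
      for (s in seq_len(detour_samples)) {
        g <- tryCatch(detour_graph(n, cc, seed = seed + 31 * cc + s),
                      error = function(e) NULL)
        if (!is.null(g)) add(g, "detour")
      }
    }
  }
  if (n >= 4) {
    for (cc in 2:(n - 2)) add(standard_detour(n, cc), "detour")
  }
  for (cc in seq_len(n - 1)) {
    for (t in 1:2) {
      if (cc + t <= n) {
        add(comet_kite(n, cc, t, seed = seed + 7 * cc + t), "comet_kite")
      }
    }
    add(standard_kite(n, cc), "comet_kite")
  }
  # generalized stars outrank coupled stars so that the plain star (the
  # degenerate a = 0 coupled star) carries its usual family tag
  pri <- c(generalized_star = 1, coupled_star = 2, detour = 3, comet_kite = 4)
  purrr::map_dfr(rows, ~ tibble::tibble(graph6 = .x[1], category = .x[2])) |>
    dplyr::arrange(pri[.data$category]) |>
    dplyr::distinct(.data$graph6, .keep_all = TRUE)
}
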