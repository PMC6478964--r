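# Genetic algorithm over the space of connected graphs of fixed size.
# Graphs are handled as "gene codes": indicator vectors over the C(N,2)
# possible links, the same encoding the recombination and mutation operators
# act on.

#' Genetic algorithm configuration
#'
#' Bundles and validates the GA parameters. Defaults follow the standard
#' settings (`m = 120` graphs, `k = 20` parents, `b = 1` expected mutation
#' per individual, `n_iter = 5000` generations); small sizes converge with
#' far less (`m = 40`, `k = 5`, `n_iter = 1000` suffices up to N = 10).
#'
#' @param graph_size Number of nodes N of every graph in the population.
#' @param r Relative mutant fitness.
#' @param objective `"fixation_probability"` or `"fixation_time"`.
#' @param direction `"min"` or `"max"`.
#' @param rule Update rule, `"Bd"` or `"dB"`.
#' @param m Population size (offspring per generation).
#' @param k Parents per generation, `2 <= k <= m`.
#' @param b Mean mutations per individual per generation; every possible link
#'   toggles independently with probability `b / choose(N, 2)`, so the number
#'   of mutations is binomial with mean `b`.
#' @param n_iter Number of generations.
#' @param init_p Link probability of the Erdos-Renyi initial population.
#' @param seed Optional integer seed; fixes the whole run.
#' @param max_nodes Passed to the exact solver.
#' @return An object of class `evo_ga_config`.
#' @export
ga_config <- function(graph_size, r,
                      objective = c("fixation_probability", "fixation_time"),
                      direction = c("max", "min"), rule = "Bd",
                      m = 120, k = 20, b = 1, n_iter = 5000,
                      init_p = 0.5, seed = NULL, max_nodes = 16) {
  objective <- match.arg(objective)
  direction <- match.arg(direction)
  rule <- check_rule(rule)
  stopifnot(graph_size >= 3, r > 0, m >= 2, k >= 2, k <= m, b >= 0,
            b <= choose(graph_size, 2), n_iter >= 1,
            init_p > 0, init_p <= 1)
  structure(list(graph_size = as.integer(graph_size), r = r,
                 objective = objective, direction = direction, rule = rule,
                 m = as.integer(m), k = as.integer(k), b = b,
                 n_iter = as.integer(n_iter), init_p = init_p, seed = seed,
                 max_nodes = max_nodes),
            class = "evo_ga_config")
}

#' Recombine two graphs
#'
#' Offspring inherit each of the `choose(N, 2)` potential links from either
#' parent with probability 1/2; disconnected results are recreated until
#' connected. The offspring's edge set therefore always lies between the
#' intersection and the union of the parents' edge sets.
#'
#' @param parent_a,parent_b Graphs on the same number of nodes.
#' @param max_tries Resampling budget.
#' @return An `igraph` graph.
#' @export
recombine <- function(parent_a, parent_b, max_tries = 1000) {
  n <- igraph::vcount(parent_a)
  if (igraph::vcount(parent_b) != n) {
    stop("parents must have the same number of nodes", call. = FALSE)
  }
  pairs <- pair_index(n)
  ba <- bits_from_graph(parent_a)
  bb <- bits_from_graph(parent_b)
  for (i in seq_len(max_tries)) {
    take_b <- runif(length(ba)) < 0.5
    child <- ba
    child[take_b] <- bb[take_b]
    if (bits_connected(child, n, pairs)) return(graph_from_bits(child, n, pairs))
  }
  stop("recombination failed to produce a connected graph", call. = FALSE)
}

#' Mutate a graph
#'
#' Toggles every potential link independently with probability
#' `b / choose(N, 2)` (so the mutation count is binomial with mean `b`) and
#' resamples until the result is connected. A disconnected graph has no
#' defined fixation dynamics here, hence the connectivity constraint also
#' applies after mutation.
#'
#' @param g A connected graph.
#' @param b Mean number of mutations, `0 <= b <= choose(N, 2)`.
#' @param max_tries Resampling budget.
#' @return An `igraph` graph.
#' @export
mutate_graph <- function(g, b, max_tries = 1000) {
  n <- igraph::vcount(g)
  np <- choose(n, 2)
  if (b < 0 || b > np) stop("`b` must lie in [0, choose(N, 2)]", call. = FALSE)
  if (b == 0) return(g)
  pairs <- pair_index(n)
  bits <- bits_from_graph(g)
  for (i in seq_len(max_tries)) {
    child <- xor(bits, runif(np) < b / np)
    if (bits_connected(child, n, pairs)) return(graph_from_bits(child, n, pairs))
  }
  stop("mutation failed to produce a connected graph", call. = FALSE)
}

#' Run the genetic algorithm
#'
#' Starts from `m` connected Erdos-Renyi graphs and iterates: score every
#' graph exactly with the Markov-chain solver, keep the best `k` as parents
#' (elitism: parents stay in the evaluated pool next to their offspring, so
#' the best score is weakly monotone across generations), create `m`
#' offspring by recombining two distinct parents drawn uniformly from the
#' top k, and mutate each offspring. Ties in score are broken toward the
#' lexicographically smallest canonical graph6 string, which makes runs
#' fully deterministic given the seed. Isomorphic graphs are never solved
#' twice: scores are cached by canonical label.
#'
#' @param config An [ga_config()] object.
#' @return An object of class `evo_ga`: list with `best_graph` (canonical
#'   `igraph`), `best_graph6`, `best_score`, `trace` (tibble of per-generation
#'   best scores), `evaluations` (distinct isomorphism classes scored), and
#'   `config`. See [tidy.evo_ga()], [glance.evo_ga()], [autoplot.evo_ga()].
#' @examples
#' \donttest{
#' cfg <- ga_config(5, r = 1.25, objective = "fixation_probability",
#'                  direction = "max", m = 20, k = 4, n_iter = 50, seed = 1)
#' run_ga(cfg)$best_graph6  # the star
#' }
#' @export
run_ga <- function(config) {
  stopifnot(inherits(config, "evo_ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$graph_size
  pairs <- pair_index(n)
  np <- nrow(pairs)
  m <- config$m
  k <- config$k
  sgn <- if (config$direction == "max") -1 else 1
  want_tau <- config$objective == "fixation_time"

  label_env <- cache_env(paste0("label", n))
  run_labels <- new.env(parent = emptyenv())

  score_pool <- function(bits) {
    keys <- apply(bits, 1, function(b) rawToChar(as.raw(b + 48L)))
    labs <- character(length(keys))
    for (i in seq_along(keys)) {
      lab <- label_env[[keys[i]]]
      if (is.null(lab)) {
        lab <- canonical_label(graph_from_bits(bits[i, ], n, pairs))
        label_env[[keys[i]]] <- lab
      }
      labs[i] <- lab
    }
    sc <- numeric(length(labs))
    for (i in seq_along(labs)) {
      v <- fixation_uniform_cached(labs[i], config$r, config$rule,
                                   max_nodes = config$max_nodes)
      sc[i] <- if (want_tau) v[["tau"]] else v[["phi"]]
      if (is.null(run_labels[[labs[i]]])) run_labels[[labs[i]]] <- TRUE
    }
    list(score = sc, label = labs)
  }

  draw_connected <- function(k_rows, maker, max_tries = 1000) {
    # maker(idx) returns a logical matrix of candidate rows for `idx`
    out <- maker(k_rows)
    for (tries in seq_len(max_tries)) {
      ok <- connected_rows_cpp(out, pairs, n)
      if (all(ok)) return(out)
      redo <- which(!ok)
      out[redo, ] <- maker(redo)
    }
    stop("failed to produce connected offspring", call. = FALSE)
  }

  # initial population
  pop <- matrix(FALSE, m, np)
  for (i in seq_len(m)) {
    pop[i, ] <- bits_from_graph(erdos_renyi_connected(n, config$init_p))
  }

  parents <- NULL
  best_score <- NA_real_
  best_label <- NA_character_
  trace <- numeric(config$n_iter)

  for (gen in seq_len(config$n_iter)) {
    pool <- rbind(parents, pop)
    ev <- score_pool(pool)
    ord <- order(sgn * ev$score, ev$label, method = "radix")
    top_i <- ord[1]
    if (is.na(best_score) ||
        sgn * ev$score[top_i] < sgn * best_score ||
        (ev$score[top_i] == best_score && ev$label[top_i] < best_label)) {
      best_score <- ev$score[top_i]
      best_label <- ev$label[top_i]
    }
    trace[gen] <- ev$score[top_i]
    parents <- pool[ord[seq_len(k)], , drop = FALSE]

    ia <- sample.int(k, m, replace = TRUE)
    ib <- (ia - 1L + sample.int(k - 1L, m, replace = TRUE)) %% k + 1L
    children <- draw_connected(seq_len(m), function(idx) {
      pa <- parents[ia[idx], , drop = FALSE]
      pb <- parents[ib[idx], , drop = FALSE]
      take <- matrix(runif(length(idx) * np) < 0.5, length(idx), np)
      pa[take] <- pb[take]
      pa
    })
    pm <- config$b / np
    pop <- draw_connected(seq_len(m), function(idx) {
      xor(children[idx, , drop = FALSE],
          matrix(runif(length(idx) * np) < pm, length(idx), np))
    })
  }

  structure(list(best_graph = parse_graph6(best_label),
                 best_graph6 = best_label,
                 best_score = best_score,
                 trace = tibble::tibble(generation = seq_len(config$n_iter),
                                        best_score = trace),
                 evaluations = length(ls(run_labels)),
                 config = config),
            class = "evo_ga")
}

#' @export
print.evo_ga <- function(x, ...) {
  cfg <- x$config
  cat("Genetic algorithm run (N = ", cfg$graph_size, ", r = ", format(cfg$r),
      ", ", cfg$rule, ")\n", sep = "")
  cat(cfg$direction, " ", cfg$objective, " over ", cfg$n_iter,
      " generations (m = ", cfg$m, ", k = ", cfg$k, ", b = ", cfg$b, ")\n",
      sep = "")
  cat("best graph:", x$best_graph6, " score:", format(x$best_score), "\n")
  cat("distinct isomorphism classes scored:", x$evaluations, "\n")
  invisible(x)
}
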