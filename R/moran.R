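# Exact fixation probabilities and times via the full 2^N-state mutant-set
# Markov chain. States are node subsets encoded as N-bit integers (bit i-1 set
# iff node i is a mutant); the empty set and the full set are absorbing.

#' Well-mixed Moran fixation probability
#'
#' Closed form for the fixation probability of a single mutant of relative
#' fitness `r` in a well-mixed population of size N (the complete graph):
#' \deqn{\phi = \frac{1 - 1/r}{1 - r^{-N}}}{phi = (1 - 1/r) / (1 - r^-N)}
#' with the neutral limit 1/N at r = 1. By the isothermal property, every
#' regular graph has this same uniform fixation probability under Bd updating.
#'
#' @param n Population size N >= 2.
#' @param r Relative mutant fitness, r > 0 (vectorized).
#' @return Fixation probability (same length as `r`).
#' @export
moran_complete <- function(n, r) {
  if (length(n) != 1 || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  ifelse(abs(r - 1) < 1e-12, 1 / n, (1 - 1 / r) / (1 - r^(-n)))
}

check_rule <- function(rule) {
  match.arg(rule, c("Bd", "dB"))
}

# state membership matrix: 2^n x n logical, row s+1 = bits of s (cached per n)
state_matrix <- function(n) {
  e <- cache_env("states")
  key <- as.character(n)
  M <- e[[key]]
  if (!is.null(M)) return(M)
  s <- 0:(2^n - 1)
  M <- vapply(seq_len(n), function(j) bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L,
              logical(length(s))) * 1
  e[[key]] <- M
  M
}

kernel_matrices <- function(g, r, rule) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(A)
  M <- state_matrix(n)
  k <- M %*% rep(1, n)
  if (rule == "Bd") {
    # gain of j not in S: (r/F) * sum_{i in S, i~j} 1/deg(i)
    # loss of j in S:     (1/F) * sum_{i not in S, i~j} 1/deg(i)
    W <- A / deg
    F_tot <- r * k + (n - k)
    gain <- (r / F_tot)[, 1] * (M %*% W)
    loss <- (1 / F_tot)[, 1] * ((1 - M) %*% W)
  } else {
    # dB: dead node j chosen uniformly; neighbors compete by fitness
    mS <- M %*% A  # mutant neighbors of each node, per state
    degm <- matrix(deg, nrow(M), n, byrow = TRUE)
    denom <- r * mS + (degm - mS)
    gain <- (1 / n) * r * mS / denom
    loss <- (1 / n) * (degm - mS) / denom
  }
  gain[M == 1] <- 0
  loss[M == 0] <- 0
  list(gain = gain, loss = loss, n = n)
}

#' Transition kernel of the mutant-set Markov chain
#'
#' For every mutant-occupancy state S (encoded as an N-bit integer) gives the
#' probability that node j is gained (S to S + {j}) or lost (S to S - {j}) in
#' one elementary update. Under Bd, a reproducer is drawn proportional to
#' fitness from the whole graph and its offspring replaces a uniform neighbor;
#' under dB a uniform node dies and its neighbors compete proportionally to
#' fitness for the vacancy. Remaining probability mass is the self-loop. The
#' empty and full states are absorbing (all-zero rows).
#'
#' @param g A connected undirected graph.
#' @param r Relative mutant fitness, r > 0.
#' @param rule Update rule, `"Bd"` (default) or `"dB"`.
#' @param max_nodes Safety cap on N (the chain has 2^N states).
#' @return An object of class `evo_kernel`: a list with `states` (0-based
#'   bitmask integers), matrices `gain` and `loss` (2^N by N), and `n`, `r`,
#'   `rule`.
#' @examples
#' k2 <- transition_kernel(evo_graph(2, cbind(1, 2)), r = 2)
#' k2$gain[2, 2]  # state {1}: gain node 2 with prob 2/3
#' @export
transition_kernel <- function(g, r, rule = "Bd", max_nodes = 16) {
  rule <- check_rule(rule)
  n <- igraph::vcount(g)
  if (n > max_nodes) {
    stop("graph has ", n, " nodes; raise `max_nodes` to allow 2^", n,
         " states", call. = FALSE)
  }
  if (!graph_is_connected(g)) stop("graph must be connected", call. = FALSE)
  if (length(r) != 1 || r <= 0) stop("`r` must be a single positive number",
                                     call. = FALSE)
  km <- kernel_matrices(g, r, rule)
  structure(list(states = 0:(2^n - 1), gain = km$gain, loss = km$loss,
                 n = n, r = r, rule = rule),
            class = "evo_kernel")
}

#' Exact fixation probability and conditional fixation time
#'
#' Solves the absorbing Markov chain of the Moran process on `g` exactly. For
#' the fixation probability the linear system is phi(S) = sum_S' P(S->S')
#' phi(S') with phi(empty) = 0 and phi(full) = 1; for times, u(S) =
#' sum_S' P(S->S') u(S') + phi(S) with u = 0 at both absorbing states, where
#' u(S) = phi(S) * E(steps to fixation | fixation). Every elementary update
#' counts one time step, including self-replacements that do not change the
#' state. The conditional time from node i is tau_i = u({i}) / phi({i}); the
#' uniform-initialization summaries are phi = mean(phi_i) and tau =
#' sum(u_i) / sum(phi_i), i.e. the fixation-probability-weighted average of
#' the tau_i, which is the mean time conditioned on fixation when the start
#' node is uniform.
#'
#' @inheritParams transition_kernel
#' @return An object of class `evo_fixation` with per-node vectors `phi` and
#'   `tau`, scalars `phi_uniform` and `tau_uniform`, and metadata `n`, `r`,
#'   `rule`, `graph6`. See [tidy.evo_fixation()] / [glance.evo_fixation()].
#' @examples
#' fx <- fixation(evo_graph(4, t(combn(4, 2))), r = 2)  # K4
#' fx$phi_uniform  # 8/15, the well-mixed Moran value
#' @export
fixation <- function(g, r, rule = "Bd", max_nodes = 16) {
  rule <- check_rule(rule)
  n <- igraph::vcount(g)
  if (n == 1) {
    return(new_fixation(1, r, rule, phi = 1, tau = 0, write_graph6(g)))
  }
  kern <- transition_kernel(g, r, rule, max_nodes = max_nodes)
  ns <- 2^n
  full <- ns - 1
  gain <- kern$gain
  loss <- kern$loss
  q <- rowSums(gain) + rowSums(loss)

  gi <- which(gain > 0, arr.ind = TRUE)
  g_from <- gi[, 1] - 1L
  g_to <- g_from + bitwShiftL(1L, gi[, 2] - 1L)
  g_p <- gain[gi]
  li <- which(loss > 0, arr.ind = TRUE)
  l_from <- li[, 1] - 1L
  l_to <- l_from - bitwShiftL(1L, li[, 2] - 1L)
  l_p <- loss[li]

  # transient states are 1 .. ns-2 and index themselves
  b_phi <- numeric(ns - 2)
  hit_full <- g_to == full
  if (any(hit_full)) {
    b_phi[g_from[hit_full]] <- b_phi[g_from[hit_full]] + g_p[hit_full]
  }
  keep_g <- !hit_full
  keep_l <- l_to != 0L
  ii <- c(seq_len(ns - 2), g_from[keep_g], l_from[keep_l])
  jj <- c(seq_len(ns - 2), g_to[keep_g], l_to[keep_l])
  xx <- c(q[2:(ns - 1)], -g_p[keep_g], -l_p[keep_l])

  if (ns <= 2048) {
    Amat <- matrix(0, ns - 2, ns - 2)
    Amat[cbind(ii, jj)] <- xx
    phi_t <- solve(Amat, b_phi)
    u_t <- solve(Amat, phi_t)
  } else {
    Amat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(ns - 2, ns - 2))
    phi_t <- as.vector(Matrix::solve(Amat, b_phi))
    u_t <- as.vector(Matrix::solve(Amat, phi_t))
  }
  singles <- bitwShiftL(1L, seq_len(n) - 1L)
  phi_i <- phi_t[singles]
  u_i <- u_t[singles]
  if (any(phi_i <= 0)) {
    stop("zero fixation probability on a connected graph; solver failure",
         call. = FALSE)
  }
  new_fixation(n, r, rule, phi = phi_i, tau = u_i / phi_i,
               graph6 = write_graph6(g),
               phi_uniform = mean(phi_i),
               tau_uniform = sum(u_i) / sum(phi_i))
}

new_fixation <- function(n, r, rule, phi, tau, graph6,
                         phi_uniform = mean(phi),
                         tau_uniform = sum(phi * tau) / sum(phi)) {
  structure(list(n = n, r = r, rule = rule, phi = phi, tau = tau,
                 phi_uniform = phi_uniform, tau_uniform = tau_uniform,
                 graph6 = graph6),
            class = "evo_fixation")
}

#' @export
print.evo_fixation <- function(x, ...) {
  cat("Moran fixation (", x$rule, " updating, r = ", format(x$r), ")\n",
      sep = "")
  cat("graph6:", x$graph6, " N =", x$n, "\n")
  cat("uniform fixation probability phi =", format(x$phi_uniform), "\n")
  cat("uniform conditional time     tau =", format(x$tau_uniform), "\n")
  invisible(x)
}

# cached uniform (phi, tau) keyed by canonical graph6 + r + rule
fixation_uniform_cached <- function(g6, r, rule, max_nodes = 16) {
  e <- cache_env("fix")
  key <- paste(g6, r, rule, sep = "|")
  v <- e[[key]]
  if (is.null(v)) {
    fx <- fixation(parse_graph6(g6), r, rule, max_nodes = max_nodes)
    v <- c(phi = fx$phi_uniform, tau = fx$tau_uniform)
    e[[key]] <- v
  }
  v
}

#' Monte Carlo simulation of the Moran process
#'
#' Runs the update rule step by step from a single mutant placed uniformly at
#' random and reports the fraction of replicates that fixed and the mean
#' number of elementary steps among those, with standard errors. This is an
#' independent stochastic check of the exact solver, not a replacement for it.
#'
#' @inheritParams transition_kernel
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed (`set.seed()` is called when supplied);
#'   the same seed reproduces the run bit for bit.
#' @param max_steps Per-replicate step guard.
#' @return A one-row tibble with columns `n_reps`, `n_fixed`, `phi_hat`,
#'   `phi_se`, `tau_hat`, `tau_se`.
#' @export
simulate_moran <- function(g, r, rule = "Bd", n_reps = 10000, seed = NULL,
                           max_steps = 1e7) {
  rule <- check_rule(rule)
  if (!graph_is_connected(g)) stop("graph must be connected", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) as.integer(v) - 1L)
  res <- moran_sim_cpp(adj, r, if (rule == "Bd") 0L else 1L,
                       as.integer(n_reps), max_steps)
  nf <- res$n_fixed
  p <- nf / n_reps
  tau_hat <- if (nf > 0) res$t_sum / nf else NA_real_
  tau_se <- if (nf > 1) {
    sqrt((res$t_sumsq - res$t_sum^2 / nf) / (nf - 1) / nf)
  } else {
    NA_real_
  }
  tibble::tibble(n_reps = as.integer(n_reps), n_fixed = as.integer(nf),
                 phi_hat = p, phi_se = sqrt(p * (1 - p) / n_reps),
                 tau_hat = tau_hat, tau_se = tau_se)
}
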