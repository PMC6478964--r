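# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a fixation result
#'
#' @param x An `evo_fixation` object from [fixation()].
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `phi`, `tau`.
#' @export
tidy.evo_fixation <- function(x, ...) {
  tibble::tibble(node = seq_len(x$n), phi = x$phi, tau = x$tau)
}

#' @rdname tidy.evo_fixation
#' @return `glance()` returns a one-row tibble with `n_nodes`, `r`, `rule`,
#'   `phi_uniform`, `tau_uniform`, `graph6`.
#' @export
glance.evo_fixation <- function(x, ...) {
  tibble::tibble(n_nodes = x$n, r = x$r, rule = x$rule,
                 phi_uniform = x$phi_uniform, tau_uniform = x$tau_uniform,
                 graph6 = x$graph6)
}

#' Tidy a genetic-algorithm run
#'
#' @param x An `evo_ga` object from [run_ga()].
#' @param ... Unused.
#' @return The per-generation trace as a tibble (`generation`, `best_score`).
#' @export
tidy.evo_ga <- function(x, ...) {
  x$trace
}

#' @rdname tidy.evo_ga
#' @export
glance.evo_ga <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(graph_size = cfg$graph_size, r = cfg$r, rule = cfg$rule,
                 objective = cfg$objective, direction = cfg$direction,
                 n_iter = cfg$n_iter, best_score = x$best_score,
                 best_graph6 = x$best_graph6, evaluations = x$evaluations)
}

#' Tidy a classification result
#'
#' @param x An `evo_class` object from [classify_graph()].
#' @param ... Unused.
#' @return A tibble with one row per grid point: `r`, `phi`, `phi_complete`,
#'   `delta`.
#' @export
tidy.evo_class <- function(x, ...) {
  tibble::tibble(r = x$r_grid, phi = x$phi, phi_complete = x$phi_complete,
                 delta = x$delta)
}

#' @rdname tidy.evo_class
#' @export
glance.evo_class <- function(x, ...) {
  tibble::tibble(graph6 = x$graph6, n_nodes = x$n, rule = x$rule,
                 verdict = x$verdict,
                 crossing_lo = if (is.null(x$crossing_r)) NA_real_ else
                   x$crossing_r[1],
                 crossing_hi = if (is.null(x$crossing_r)) NA_real_ else
                   x$crossing_r[2])
}

#' Tidy a temperature profile
#'
#' @param x An `evo_temperature` object from [temperature_profile()].
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `temperature`.
#' @export
tidy.evo_temperature <- function(x, ...) {
  tibble::tibble(node = seq_len(x$n), temperature = x$temperature)
}

#' Plot the probability-time plane
#'
#' Scatter of mean conditional fixation time against fixation probability,
#' one point per isomorphism class, echoing the map of the universe of
#' evolutionary graphs: extremal families in color, graphs with a pendant
#' node in light gray, everything else in dark gray, the complete graph's
#' values as dashed reference lines.
#'
#' @param object An `evo_plane` tibble from [build_plane()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evo_plane <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$shade <- ifelse(df$category != "other", df$category,
                     ifelse(df$has_pendant, "other (pendant)", "other"))
  cols <- c("generalized_star" = "#d62728", "coupled_star" = "#c510c5",
            "detour" = "#1f77b4", "comet_kite" = "#2ca02c",
            "other (pendant)" = "grey75", "other" = "grey35")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$tau,
                                   color = .data$shade)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = attr(object, "phi_complete"),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_hline(yintercept = attr(object, "tau_complete"),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_color_manual(values = cols, name = "category") +
    ggplot2::labs(
      x = "fixation probability",
      y = "mean conditional fixation time",
      title = sprintf("All connected graphs of size %d (r = %s, %s)",
                      attr(object, "n"), format(attr(object, "r")),
                      attr(object, "rule"))) +
    ggplot2::theme_minimal()
}

#' Plot a genetic-algorithm trace
#'
#' @param object An `evo_ga` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evo_ga <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation",
                  y = paste(object$config$direction,
                            object$config$objective)) +
    ggplot2::theme_minimal()
}

#' Plot a classification result
#'
#' Difference to the complete graph's fixation probability across the fitness
#' grid; a sign change right of r = 1 is the piecewise-suppressor signature.
#'
#' @param object An `evo_class` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evo_class <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mutant fitness r",
                  y = expression(phi - phi[complete]),
                  title = paste("verdict:", object$verdict)) +
    ggplot2::theme_minimal()
}
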