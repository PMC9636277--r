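#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a strategy distribution
#'
#' @param x A `strategy_distribution`.
#' @param ... Unused.
#' @return The abundance tibble (`id`, `label`, `abundance`), sorted by
#'   decreasing abundance.
#' @export
tidy.strategy_distribution <- function(x, ...) {
  dplyr::arrange(x$abundance, dplyr::desc(.data$abundance))
}

#' One-row summary of a strategy distribution
#'
#' @inheritParams tidy.strategy_distribution
#' @return A one-row tibble: the run parameters, the most abundant strategy,
#'   and the mean cooperation level.
#' @export
glance.strategy_distribution <- function(x, ...) {
  top <- dplyr::slice_max(x$abundance, .data$abundance, n = 1, with_ties = FALSE)
  p <- x$params
  tibble::tibble(
    N = p$N, M = p$M, b = p$b, sigma_in = p$sigma_in, sigma_out = p$sigma_out,
    e = p$e,
    top_strategy = top$label, top_abundance = top$abundance,
    mean_cooperation = mean_cooperation(x, e = p$e)
  )
}

#' Bar chart of strategy abundances
#'
#' @param object A `strategy_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strategy_distribution <- function(object, ...) {
  tab <- object$abundance
  tab$label <- factor(tab$label, levels = tab$label)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$abundance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "stationary abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Tidy a transition graph
#'
#' @param x A `transition_graph`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.transition_graph <- function(x, ...) x$edges

#' Diagram of above-threshold fixation-probability edges
#'
#' Nodes are placed on a circle; arrows run from the resident strategy to
#' the invading mutant, with width proportional to the fixation probability.
#'
#' @param object A `transition_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_graph <- function(object, ...) {
  edges <- dplyr::filter(object$edges, .data$above)
  nodes <- unique(c(object$edges$from, object$edges$to))
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(label = nodes, x = cos(ang), y = sin(ang))
  edges <- dplyr::left_join(edges, pos, by = c("from" = "label"))
  edges <- dplyr::left_join(edges, pos, by = c("to" = "label"),
                            suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$psi),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      alpha = 0.6) +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$label)) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Cooperation level versus group size for a sweep table
#'
#' @param object A tibble returned by [sweep_cooperation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$N, y = .data$mean_cooperation,
                               colour = factor(.data$b))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "group size N", y = "mean cooperation",
                  colour = "benefit b") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
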