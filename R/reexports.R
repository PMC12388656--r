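#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL

#' Stacked-bar view of assembly-process fractions per group
#' @param object an `assembly_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.assembly_result <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "Fraction of pairs",
                  fill = "Assembly process") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Force-layout view of a correlation network
#' @param object an `assembly_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.assembly_network <- function(object, seed = 1, ...) {
  g <- object$graph
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nodes$x[match(ed$from, nodes$name)]
  ed$y <- nodes$y[match(ed$from, nodes$name)]
  ed$xend <- nodes$x[match(ed$to, nodes$name)]
  ed$yend <- nodes$y[match(ed$to, nodes$name)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend,
                   colour = factor(.data$sign)),
      alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`-1` = "#c62828",
                                            `1` = "#2e7d32"),
                                 labels = c(`-1` = "negative",
                                            `1` = "positive")) +
    ggplot2::labs(colour = "Edge sign") +
    ggplot2::theme_void()
  size_col <- nodes$mean_rel_abundance
  if (all(is.na(size_col))) size_col <- 1
  p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, size = size_col),
    alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.5, 4),
                                   name = "Mean rel. abundance")
}
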