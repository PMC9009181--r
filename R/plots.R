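#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_text
#'   geom_col labs theme_minimal scale_size_continuous
#' @export
ggplot2::autoplot

#' Plot a median haplotype network
#'
#' Fruchterman-Reingold layout (deterministic seed); observed haplotypes
#' as labelled points, inferred median vectors as small open points, edges
#' annotated with their mutation labels.
#'
#' @param object A [build_network()] result.
#' @param label_edges Draw the per-edge mutation labels.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot haplotype_network
#' @export
autoplot.haplotype_network <- function(object, label_edges = TRUE, ...) {
  g <- object$graph
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[match(nodes$node, igraph::V(g)$name), 1L]
  nodes$y <- xy[match(nodes$node, igraph::V(g)$name), 2L]
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$node)]
  edges$y <- nodes$y[match(edges$from, nodes$node)]
  edges$xend <- nodes$x[match(edges$to, nodes$node)]
  edges$yend <- nodes$y[match(edges$to, nodes$node)]
  p <- ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey50") +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, shape = .data$observed,
                   size = ifelse(.data$observed, 3, 1.5))) +
    geom_text(data = nodes[nodes$observed, ],
              aes(x = .data$x, y = .data$y, label = .data$node),
              vjust = -1, size = 3) +
    scale_size_continuous(range = c(1.5, 3), guide = "none") +
    labs(shape = "observed", x = NULL, y = NULL,
         title = "Median haplotype network") +
    theme_minimal()
  if (label_edges)
    p <- p + geom_text(data = edges,
                       aes(x = (.data$x + .data$xend) / 2,
                           y = (.data$y + .data$yend) / 2,
                           label = .data$label),
                       size = 2.4, colour = "grey30")
  p
}

#' Plot per-column information content of a domain logo
#'
#' @param object A [logo_information()] result.
#' @param ... Ignored.
#' @return A ggplot object (bits per column).
#' @method autoplot flavhap_logo
#' @export
autoplot.flavhap_logo <- function(object, ...) {
  ggplot(object$information, aes(x = .data$column, y = .data$bits)) +
    geom_col(fill = "steelblue") +
    labs(x = "alignment column", y = "information (bits)",
         title = sprintf("Sequence logo information (n = %d)", object$n)) +
    theme_minimal()
}
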