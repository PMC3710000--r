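#' Plot a signed network
#'
#' Force-directed layout (igraph Fruchterman-Reingold) with activating
#' edges drawn solid and inhibiting edges dashed.
#'
#' @param object a [signed_digraph()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.signed_digraph <- function(object, ...) {
  ig <- as_igraph(object)
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble::tibble(node = object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges %>%
    dplyr::left_join(nodes, by = c(from = "node")) %>%
    dplyr::left_join(nodes, by = c(to = "node"), suffix = c("", "end")) %>%
    dplyr::mutate(relation = ifelse(.data$sign > 0, "activation", "inhibition"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$relation),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(linetype = NULL)
}

#' Plot motif instance counts of an analysis report
#'
#' Bar chart of instance counts per query motif, grouped by regulatory
#' class; motifs without instances are omitted.
#'
#' @param object a `regmotif_report` from [analyze_network()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.regmotif_report <- function(object, ...) {
  df <- object$counts[object$counts$n_instances > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$motif_id, .data$n_instances),
                                   y = .data$n_instances, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "motif instances", fill = "class") +
    ggplot2::theme_minimal()
}
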