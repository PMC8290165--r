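#' Plot a vascular graph as a 2D projection
#'
#' Projects node positions onto the x-y plane and draws the simple edge set;
#' node colour encodes kind. A quick-look diagnostic, not a rendering of
#' vessel geometry.
#'
#' @param object a `vascular_graph`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vascular_graph <- function(object, ...) {
  nd <- object$nodes
  ed <- object$edges |>
    dplyr::left_join(nd, by = c("u" = "id")) |>
    dplyr::left_join(nd, by = c("v" = "id"), suffix = c("", "_v"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_v, yend = .data$y_v),
                          colour = "grey40") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$kind),
                        size = 1.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (voxels)", y = "y (voxels)",
                  title = sprintf("%d nodes, %d edges, %d components",
                                  nrow(nd), nrow(object$edges),
                                  object$n_components)) +
    ggplot2::theme_minimal()
}

#' Plot a two-group comparison set
#'
#' One panel per metric: per-specimen points with group medians, annotated
#' with the test used and its p-value.
#'
#' @param object a `group_comparison_set` from [batch_compare()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison_set <- function(object, ...) {
  long <- dplyr::bind_rows(lapply(object$comparisons, function(cmp) {
    tibble::tibble(
      metric = cmp$metric_name,
      group = rep(cmp$group_labels, c(length(cmp$samples$a),
                                      length(cmp$samples$b))),
      value = c(cmp$samples$a, cmp$samples$b),
      label = sprintf("%s\n%s P=%.3g", cmp$metric_name, cmp$test_used,
                      cmp$p_value))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.35, linewidth = 0.3, colour = "red3") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
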