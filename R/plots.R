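#' Plot a recommendation bundle
#'
#' Bar chart of similarity scores by rank, one facet per list (merged and/or
#' per cluster), colored by the source cluster.
#'
#' @param object A `recommendation_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recommendation_bundle <- function(object, ...) {
  tab <- tidy(object)
  if (nrow(tab) == 0L) abort("Nothing to plot: the bundle is empty.")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rank, y = .data$score,
                                    fill = .data$source_cluster)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$list)) +
    ggplot2::scale_x_continuous(breaks = scales_breaks(max(tab$rank))) +
    ggplot2::labs(x = "rank", y = "cosine similarity", fill = "cluster",
                  title = sprintf("Dataset recommendations (%s)", object$mode)) +
    ggplot2::theme_minimal()
}

scales_breaks <- function(n) unique(round(seq(1, n, length.out = min(n, 10))))

#' Plot cluster sizes of a partition
#'
#' @param object A `cluster_set`.
#' @param ... Unused.
#' @return A ggplot object (bar chart of cluster sizes; pruned clusters
#'   shown hollow).
#' @export
autoplot.cluster_set <- function(object, ...) {
  tab <- tibble(cluster = factor(names(object$sizes),
                                 levels = names(sort(object$sizes, decreasing = TRUE))),
                size = as.integer(object$sizes),
                eligible = names(object$sizes) %in% as.character(object$eligible))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cluster, y = .data$size,
                                    alpha = .data$eligible)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = "cluster", y = "papers", alpha = "eligible",
                  title = sprintf("Publication clusters (%s, alpha = %s)",
                                  object$method,
                                  formatC(object$alpha, digits = 3, format = "g"))) +
    ggplot2::theme_minimal()
}
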