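#' Plot a non-nested cluster tree
#'
#' Draws each clustering level as a row of tiles whose widths are
#' proportional to cluster sizes, stacked by k from the single root cluster
#' downwards, with the phi-weighted edges connecting each cluster to its
#' best-correlating parent on the level above. Best AIC / dAIC levels are
#' marked on the axis.
#'
#' @param object an `iea_tree`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.iea_tree <- function(object, ...) {
  n <- nrow(object$matrix)
  nodes <- purrr::map_dfr(object$levels, function(lv) {
    sizes <- cluster_sizes(lv)
    idx <- which(sizes > 0)
    ends <- cumsum(sizes[idx])
    tibble::tibble(
      level = lv$k_requested,
      cluster = idx,
      size = sizes[idx],
      xmin = c(0, utils::head(ends, -1L)) / n,
      xmax = ends / n
    )
  })
  nodes$x <- (nodes$xmin + nodes$xmax) / 2
  edges <- dplyr::left_join(
    object$edges,
    dplyr::select(nodes, "level", "cluster", px = "x"),
    by = c(parent_level = "level", parent_cluster = "cluster"))
  edges <- dplyr::left_join(
    edges,
    dplyr::select(nodes, "level", "cluster", cx = "x"),
    by = c(child_level = "level", child_cluster = "cluster"))
  lab <- function(k) {
    marks <- c(if (k == object$best_aic_level) "AIC",
               if (k == object$best_daic_level) "dAIC")
    if (length(marks)) sprintf("k = %d (%s)", k, paste(marks, collapse = ", ")) else sprintf("k = %d", k)
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$px, y = -.data$parent_level,
                   xend = .data$cx, yend = -.data$child_level,
                   linewidth = abs(.data$phi)),
      colour = "grey55") +
    ggplot2::geom_rect(
      data = nodes,
      ggplot2::aes(xmin = .data$xmin + 0.004, xmax = .data$xmax - 0.004,
                   ymin = -.data$level - 0.28, ymax = -.data$level + 0.28,
                   fill = factor(.data$cluster)),
      colour = "grey20", show.legend = FALSE) +
    ggplot2::scale_y_continuous(
      breaks = -seq_along(object$levels),
      labels = vapply(seq_along(object$levels), lab, character(1))) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::labs(
      title = sprintf("Cluster tree (%s annotations, %d genes)",
                      anno_system(object$matrix), n),
      x = "cumulative gene fraction", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style overview of an enrichment table
#'
#' Plots each record's annotation frequency in its cluster against the
#' FDR-adjusted p-value (log10 scale), faceted by mode, so the
#' statistically interpretable IEA hits stand apart from descriptive DEA
#' scores.
#'
#' @param records enrichment tibble from [enrich_clusters()] or the
#'   pipeline.
#' @param alpha FDR threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, alpha = 0.1) {
  stopifnot(all(c("a", "n", "p_fdr", "mode") %in% names(records)))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$a / .data$n, y = -log10(.data$p_fdr))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_fdr < alpha), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(~.data$mode) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "annotation frequency in cluster",
                  y = expression(-log[10] ~ "FDR p")) +
    ggplot2::theme_minimal()
}
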