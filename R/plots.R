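#' Stacked community-composition bars for an OTU table
#'
#' One horizontal bar per sample showing OTU relative abundances, in the
#' style of per-sample community barplots; when a taxonomy table is
#' supplied the fill is the clade.
#'
#' @param object A `symotu_table`.
#' @param tax Optional taxonomy tibble from [assign_taxonomy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symotu_table <- function(object, tax = NULL, ...) {
  rel <- relative_abundance(object)
  fill_var <- "otu_id"
  if (!is.null(tax)) {
    rel <- dplyr::left_join(rel, tax[c("otu_id", "clade")], by = "otu_id")
    fill_var <- "clade"
  }
  if (!is.null(object$metadata)) {
    rel <- dplyr::left_join(rel, object$metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(rel, ggplot2::aes(x = .data$rel_abund,
                                         y = .data$sample_id,
                                         fill = .data[[fill_var]])) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::labs(x = "Relative abundance", y = NULL,
                  fill = if (fill_var == "clade") "Clade" else "OTU") +
    ggplot2::theme_minimal()
  if ("species" %in% names(rel)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$species),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' Dispersion (symbiotic flexibility) plot
#'
#' Mean distance to centroid per group with standard-error bars, annotated
#' with compact letter display groups; groups not sharing a letter differ
#' significantly.
#'
#' @param object A `dispersion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispersion_result <- function(object, ...) {
  gs <- object$group_stats
  ggplot2::ggplot(gs, ggplot2::aes(x = stats::reorder(.data$group,
                                                      -.data$mean_dist),
                                   y = .data$mean_dist)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_dist - .data$se,
      ymax = .data$mean_dist + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean_dist + .data$se),
                       vjust = -0.8) +
    ggplot2::labs(x = NULL, y = "Mean distance to centroid") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bipartite network plot
#'
#' Hosts as squares, symbiont OTUs as circles coloured by clade, on a
#' Fruchterman-Reingold layout; edge width follows the weight where the
#' niche is weighted.
#'
#' @param object A `symbiont_network`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symbiont_network <- function(object, seed = 1L, ...) {
  lay <- layout_fr(object, seed)
  nodes <- dplyr::left_join(lay, object$nodes, by = "id")
  edges <- object$edges |>
    dplyr::left_join(lay, by = c(host = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c(symbiont = "id"))
  p <- ggplot2::ggplot()
  p <- if (all(is.na(edges$weight))) {
    p + ggplot2::geom_segment(
      data = edges, ggplot2::aes(x = .data$x0, y = .data$y0,
                                 xend = .data$x, yend = .data$y),
      colour = "grey60")
  } else {
    p + ggplot2::geom_segment(
      data = edges, ggplot2::aes(x = .data$x0, y = .data$y0,
                                 xend = .data$x, yend = .data$y,
                                 linewidth = .data$weight),
      colour = "grey60") +
      ggplot2::scale_linewidth(range = c(0.2, 1.6))
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$clade,
                   shape = .data$type,
                   size = ifelse(is.na(.data$n_species), 3,
                                 .data$n_species))) +
    ggplot2::scale_shape_manual(values = c(host = 15, symbiont = 16)) +
    ggplot2::guides(size = "none") +
    ggplot2::labs(title = paste0(object$niche, " niche"), x = NULL,
                  y = NULL) +
    ggplot2::theme_void()
}
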