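#' Heatmap of pathway enrichment scores
#'
#' Pathway-by-cultivar tile plot of PES values from [enrich()], the usual way
#' to eyeball which cultivars drive which pathways.
#'
#' @param records `bran_pes` tibble.
#' @return A ggplot object.
#' @export
plot_pes_heatmap <- function(records) {
  ggplot2::ggplot(
    as_tibble(records),
    ggplot2::aes(x = .data$cultivar, y = .data$pathway, fill = .data$score)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$score)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Discriminator counts per cultivar
#'
#' Bar chart of discriminating-metabolite entries per cultivar, split by
#' direction of the departure from the cross-cultivar mean.
#'
#' @param disc Discriminator tibble.
#' @return A ggplot object.
#' @export
plot_discriminators <- function(disc) {
  ggplot2::ggplot(
    as_tibble(disc),
    ggplot2::aes(x = .data$cultivar, fill = .data$direction)
  ) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "discriminating entries", fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Score scatter for an ordination summary
#'
#' @param object `bran_ordination` object.
#' @param ... Unused.
#' @return A ggplot object of the first two component scores with percent
#'   variance in the axis labels.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.bran_ordination <- function(object, ...) {
  v <- object$variance$var_pct
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$cultivar),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", v[1]),
      y = sprintf("PC2 (%.1f%%)", v[2])
    ) +
    ggplot2::theme_minimal()
}
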