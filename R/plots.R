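# ggplot2 displays for fitted models, explanations and evaluation results.

#' Plot the training history of a fitted model
#'
#' Loss curves per epoch (total, classification, contrastive), plus
#' validation AUC when recorded.
#'
#' @param object A `cmms_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cmms_model
#' @export
autoplot.cmms_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, cols = dplyr::starts_with("loss"),
                              names_to = "component", values_to = "value")
  long$component <- dplyr::recode(long$component, loss = "total",
                                  loss_class = "classification",
                                  loss_contr = "contrastive")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss (per molecule / per batch)",
                  colour = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot an attention explanation
#'
#' Per-atom attention weights in SMILES atom order, with atom symbols as
#' labels; useful for spotting the functional groups the sequence encoder
#' attends to.
#'
#' @param object A `cmms_explanation` from [attention_explanation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cmms_explanation
#' @export
autoplot.cmms_explanation <- function(object, ...) {
  a <- object$atoms
  ggplot2::ggplot(a, ggplot2::aes(x = .data$atom, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$symbol), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "atom (SMILES order)", y = "attention weight",
                  title = object$smiles) +
    ggplot2::theme_minimal()
}

#' Bar chart of a substructure frequency report
#'
#' @param report Tibble from [group_frequency_report()].
#' @return A ggplot object (groups ranked within predicted class).
#' @export
plot_group_frequency <- function(report) {
  report$label <- sprintf("%s (%d)", report$group, report$rank)
  ggplot2::ggplot(report,
                  ggplot2::aes(x = stats::reorder(.data$label,
                                                  .data$percent),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% of critical-bond instances",
                  title = "High-impact substructures") +
    ggplot2::theme_minimal()
}

#' Scatter plot of structural clusters
#'
#' Projects molecules onto the first two principal components of the
#' Tanimoto-similarity matrix, coloured by K-means cluster.
#'
#' @param clusters Tibble from [cluster_molecules()].
#' @return A ggplot object.
#' @export
plot_clusters <- function(clusters) {
  ev <- attr(clusters, "explained_var")
  labs <- if (!is.null(ev)) {
    sprintf(c("PC1 (%.1f%%)", "PC2 (%.1f%%)"), 100 * ev)
  } else {
    c("PC1", "PC2")
  }
  ggplot2::ggplot(clusters,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = "cluster",
                  title = "Structural clusters (ECFP-Tanimoto K-means)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
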