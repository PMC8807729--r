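## ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_vline labs
#'   theme_minimal geom_smooth geom_abline geom_segment geom_text
NULL

#' Plot a PCA fingerprint
#'
#' Scores on two components, colored by organ (the organ-specific
#' fingerprint view).
#'
#' @param object A `metallome_pca`.
#' @param components Two component indices (default PC1, PC2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metallome_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  ve <- object$variance_explained[components]
  df <- object$scores
  ggplot(df, aes(
    x = .data[[pcs[1]]], y = .data[[pcs[2]]],
    colour = .data$organ, shape = factor(.data$age_months)
  )) +
    geom_point(size = 2, alpha = 0.85) +
    labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * ve[1]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * ve[2]),
      colour = "organ", shape = "age (months)"
    ) +
    theme_minimal()
}

#' Volcano plot of age effects
#'
#' Effect (log2 fold change for concentrations, per-mil difference for
#' deltas) against -log10 adjusted p, with the significance threshold drawn
#' as a dotted line.
#'
#' @param volcano Output of [age_contrast_volcano()].
#' @param alpha Significance threshold (default 0.05).
#' @return A ggplot.
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  ggplot(volcano, aes(
    x = .data$effect, y = -log10(.data$adj_p),
    colour = .data$organ
  )) +
    geom_point(size = 2) +
    geom_text(aes(label = .data$analyte),
      vjust = -0.7, size = 2.8,
      show.legend = FALSE
    ) +
    geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "effect of aging (log2 FC / ‰ difference)", y = "-log10 Adj.P") +
    theme_minimal()
}

#' Plot a multi-layer network
#'
#' Minimal rendering: Fruchterman-Reingold layout, edge color by sign,
#' width by |weight|, node color by type.
#'
#' @param object A `multilayer_network`.
#' @param seed Layout seed (layout is stochastic).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.multilayer_network <- function(object, seed = 1, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot() +
      theme_minimal() +
      labs(title = "empty network"))
  }
  g <- as_igraph(object)
  withr::local_seed(seed)
  xy <- igraph::layout_with_fr(g, weights = NA) # signed weights: layout unweighted
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", xa = "x", ya = "y"),
      by = c(from = "id")
    ) |>
    dplyr::left_join(dplyr::select(nodes, "id", xb = "x", yb = "y"),
      by = c(to = "id")
    )
  ggplot() +
    geom_segment(
      data = edges,
      aes(
        x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        linewidth = abs(.data$weight),
        colour = factor(.data$sign, levels = c(-1, 1))
      ),
      alpha = 0.6
    ) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y, fill = .data$type),
      shape = 21, size = 4
    ) +
    geom_text(data = nodes, aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.1, size = 2.8
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::scale_colour_manual(
      values = c(`-1` = "#4575b4", `1` = "#d73027"),
      name = "sign", drop = FALSE
    ) +
    ggplot2::theme_void()
}

#' Plot a cross-study concordance report
#'
#' Per-organ scatter of the paired statistics with the OLS line and its 95%
#' confidence band, and the identity line for reference.
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$stat_a, y = .data$stat_b)) +
    geom_point(alpha = 0.6, size = 1.5) +
    geom_smooth(method = "lm", formula = y ~ x, colour = "black", linewidth = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::facet_wrap(~organ) +
    labs(
      x = "statistic, study A", y = "statistic, study B",
      title = paste0("cross-study concordance (", object$mode, ")")
    ) +
    theme_minimal()
}
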