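#' Volcano-style plot of a differential-expression result
#'
#' Diet effect size against -log10 p, colored by direction label.
#'
#' @param object a [run_de()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_diet, y = -log10(.data$p),
                                       color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(Western = "#d95f02", Mediterranean = "#1b6ca8",
                                           NS = "grey70")) +
    ggplot2::labs(x = expression(beta[diet] ~ "(log2, Western high)"),
                  y = expression(-log[10] ~ p), color = "direction") +
    ggplot2::theme_minimal()
}

#' Plot DAB scores by diet with component loadings
#'
#' @param object a [behavior_pca_dab()] result.
#' @param diet optional diet labels named by animal id for coloring.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dab_scores
#' @export
autoplot.dab_scores <- function(object, diet = NULL, ...) {
  df <- object$dab
  if (!is.null(diet)) {
    df$diet <- if (!is.null(names(diet))) diet[df$animal_id] else diet
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$diet, y = .data$dab, color = .data$diet))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$dab))
  }
  p + ggplot2::geom_boxplot(outlier.shape = NA, color = "grey40") +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(y = sprintf("DAB score (PC%d, %.0f%% of variance)",
                              object$dab_component,
                              100 * object$variance_explained[object$dab_component]),
                  x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot mediation proportions by gene direction
#'
#' Distribution of the proportion of the diet effect transmitted through the
#' mediator for genes whose bootstrap CI excludes zero.
#'
#' @param scan a [mediation_scan()] result.
#' @param de optional [run_de()] result supplying direction labels.
#' @return a ggplot object.
#' @export
plot_mediation <- function(scan, de = NULL) {
  df <- filter(scan, .data$significant)
  df$group <- if (!is.null(de)) de$direction[match(df$gene, de$gene)] else "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = 100 * abs(.data$proportion_mediated))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "% of diet effect mediated") +
    ggplot2::theme_minimal()
}
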