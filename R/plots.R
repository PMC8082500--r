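#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the scale-free fit across candidate soft powers
#'
#' @param object A `soft_threshold` object.
#' @param ... Unused.
#' @return A ggplot: signed scale-free fit R-squared against the power,
#'   with the selection goal and the chosen power marked.
#' @export
autoplot.soft_threshold <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$beta, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = object$r2_goal, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_vline(xintercept = object$beta, linetype = "dotted") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "soft-thresholding power",
                  y = "scale-free fit (signed R²)",
                  title = paste0("Selected power: ", object$beta)) +
    ggplot2::theme_minimal()
}

#' Plot a triad significance profile
#'
#' @param object A `triad_significance` tibble.
#' @param ... Unused.
#' @return A ggplot of the length-normalized Z vector over the 13 triad
#'   classes, significant classes highlighted.
#' @export
autoplot.triad_significance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- pmin(df$p_over, df$p_under) < 1 / attr(object, "n_random")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_id, y = .data$sp)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_x_continuous(breaks = 1:13, labels = df$name) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = "normalized Z (SP)",
                  title = "Triad significance profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot fuzzy expression-pattern clusters
#'
#' @param object A `fuzzy_clustering` object.
#' @param ... Unused.
#' @return A ggplot of the cluster centroid profiles, one panel per
#'   cluster.
#' @export
autoplot.fuzzy_clustering <- function(object, ...) {
  tissues <- colnames(object$centroids)
  cent <- tibble::tibble(
    cluster = rep(rownames(object$centroids), each = length(tissues)),
    tissue = factor(rep(tissues, times = nrow(object$centroids)),
                    levels = tissues),
    value = as.vector(t(object$centroids))
  )
  ggplot2::ggplot(cent, ggplot2::aes(x = .data$tissue, y = .data$value,
                                     group = .data$cluster)) +
    ggplot2::geom_line(colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized expression",
                  title = "Cluster centroid profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
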