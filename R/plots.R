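#' Volcano plot
#'
#' @param x a `volcano_table` from [volcano_table()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
plot_volcano <- function(x, ...) {
  stopifnot(inherits(x, "volcano_table"))
  cut <- attr(x, "cutoffs")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(-cut["fc"], cut["fc"]), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(cut["p"]), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            ns = "grey60")) +
    ggplot2::labs(x = paste0("log2 fold change (", attr(x, "contrast"), ")"),
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.volcano_table <- function(object, ...) plot_volcano(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.outlier_result <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2, colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outlier), size = 2) +
    ggplot2::geom_point(data = object$centroids,
                        ggplot2::aes(x = .data$axis1, y = .data$axis2),
                        shape = 3, size = 4, stroke = 1.2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "PCo 1", y = "PCo 2",
                  title = sprintf("Group-dependent outliers (%s distance, x = %g)",
                                  object$metric, object$x)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.latent_model <- function(object, comps = c(1, 2), ...) {
  sc <- object$scores
  cx <- paste0("comp", comps[1]); cy <- paste0("comp", comps[2])
  lab <- function(i) {
    ev <- object$explained_variance
    if (is.null(ev) || length(ev) < comps[i]) paste0("component ", comps[i])
    else sprintf("component %d (%.1f%%)", comps[i], 100 * ev[comps[i]])
  }
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[cx]], y = .data[[cy]],
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.95, na.rm = TRUE) +
    ggplot2::labs(x = lab(1), y = lab(2), title = toupper(object$method)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2,
                               colour = factor(.data$cluster), shape = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "cluster",
                  title = sprintf("k-means (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Within-cluster sum of squares (elbow) curve
#'
#' @param x a `cluster_result` from [kmeans_clusters()].
#' @return A ggplot.
#' @export
plot_elbow <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  ggplot2::ggplot(x$wss, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$k, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "k", y = "within-cluster SS") +
    ggplot2::theme_minimal()
}

#' Correlation network plot
#'
#' Draws an `edge_table` (from [correlation_network()] or [ggm_network()]'s
#' edges) as a circular-layout graph.
#'
#' @param edges an `edge_table` tibble with `feature_i`, `feature_j` and a
#'   weight column (`r` or `partial_cor`).
#' @return A ggplot.
#' @export
plot_network <- function(edges) {
  wcol <- intersect(c("r", "partial_cor"), names(edges))[1]
  nodes <- sort(unique(c(edges$feature_i, edges$feature_j)))
  th <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(feature = nodes, px = cos(th), py = sin(th))
  seg <- edges |>
    dplyr::left_join(pos, by = c(feature_i = "feature")) |>
    dplyr::rename(x = "px", y = "py") |>
    dplyr::left_join(pos, by = c(feature_j = "feature")) |>
    dplyr::rename(xend = "px", yend = "py")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                                       yend = .data$yend, colour = .data[[wcol]],
                                       linewidth = abs(.data[[wcol]]))) +
    ggplot2::geom_point(data = pos, ggplot2::aes(x = .data$px, y = .data$py), size = 2) +
    ggplot2::geom_text(data = pos, ggplot2::aes(x = 1.08 * .data$px, y = 1.08 * .data$py,
                                                label = .data$feature), size = 3) +
    ggplot2::scale_colour_gradient2(low = "#0570b0", high = "#d7301f", mid = "grey85") +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
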