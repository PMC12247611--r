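# ggplot2 displays: centile fan plots, PR curves, correlation heatmap.

#' Centile plot of a fitted normative model
#'
#' Draws the fitted centile fan across age with the subjects overlaid;
#' when the data carry a `true_category` (or `category`) column the
#' points are coloured by it, mirroring outlier-annotated normative
#' plots.
#'
#' @param object A fitted `normative_model`.
#' @param data Optional data frame of subjects to overlay.
#' @param levels Centile levels to draw.
#' @param n_grid Age-grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.normative_model <- function(object, data = NULL,
                                     levels = c(1, 5, 25, 50, 75, 95, 99),
                                     n_grid = 120, ...) {
  grid <- seq(object$basis$domain[1], object$basis$domain[2],
              length.out = n_grid)
  cent <- compute_centiles(object, grid, levels = levels)
  p <- ggplot2::ggplot(cent, ggplot2::aes(x = .data$age, y = .data$value,
                                          group = .data$level)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$level == 50),
                       colour = "grey40", show.legend = FALSE) +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 0.9, `FALSE` = 0.3)) +
    ggplot2::labs(x = object$age_col %||% "age", y = object$idp %||% "value",
                  title = sprintf("Normative centiles: %s",
                                  object$idp %||% "")) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    cat_col <- intersect(c("true_category", "category"), names(data))[1]
    pts <- tibble(age = data[[object$age_col]], y = data[[object$idp]])
    if (!is.na(cat_col)) {
      pts$category <- data[[cat_col]]
      p <- p + ggplot2::geom_point(
        data = pts, ggplot2::aes(x = .data$age, y = .data$y,
                                 colour = .data$category),
        inherit.aes = FALSE, alpha = 0.6, size = 0.8)
    } else {
      p <- p + ggplot2::geom_point(
        data = pts, ggplot2::aes(x = .data$age, y = .data$y),
        inherit.aes = FALSE, alpha = 0.4, size = 0.8, colour = "grey25")
    }
  }
  p
}

#' Plot precision-recall curves from a threshold sweep
#'
#' @param sweep Output of [pr_threshold_sweep()].
#' @return A ggplot object with one curve per method.
#' @export
plot_pr_curves <- function(sweep) {
  curves <- sweep |>
    dplyr::mutate(curve = purrr::map2(.data$curve, .data$method,
                                      ~dplyr::mutate(.x, method = .y))) |>
    dplyr::pull("curve") |>
    dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$recall,
                                       y = .data$precision,
                                       colour = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Heatmap of the QC-measure correlation matrix
#'
#' @param corr Symmetric correlation matrix from
#'   [qc_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_qc_correlation <- function(corr) {
  df <- as.data.frame(as.table(corr))
  names(df) <- c("row", "col", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
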