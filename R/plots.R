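# ggplot2 displays for the main result types.

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity` object.
#' @param matrix Which view to draw: `"r"`, `"binary"`, or `"weighted"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot connectivity
#' @export
autoplot.connectivity <- function(object, matrix = c("r", "binary",
                                                     "weighted"), ...) {
  matrix <- match.arg(matrix)
  m <- object[[matrix]]
  if (is.null(m)) {
    rlang::abort(sprintf("matrix '%s' not present; threshold first", matrix))
  }
  df <- tidyr::expand_grid(roi_i = object$labels, roi_j = object$labels)
  df$value <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$roi_j, levels = object$labels),
    y = factor(.data$roi_i, levels = rev(object$labels)),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = matrix) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Group means of global graph metrics
#'
#' Point-and-error-bar display (mean +/- standard error) of each global
#' metric by group, faceted by graph mode.
#'
#' @param metrics Tidy metrics tibble from [cohort_graph_metrics()].
#' @return A ggplot object.
#' @export
plot_global_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics,
    cols = dplyr::all_of(c("cp", "lp", "gamma", "lambda", "sigma", "eg",
                           "eloc")),
    names_to = "metric", values_to = "value"
  )
  summ <- long |>
    dplyr::group_by(.data$graph_mode, .data$metric, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$metric, y = .data$mean,
                                     color = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.25, position = ggplot2::position_dodge(0.5)
    ) +
    ggplot2::facet_wrap(~graph_mode, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SE") +
    ggplot2::theme_bw()
}

#' Group-mean nodal degree by ROI
#'
#' @param nodal Long nodal tibble from [cohort_nodal_degree()].
#' @return A ggplot object.
#' @export
plot_nodal_degree <- function(nodal) {
  summ <- nodal |>
    dplyr::group_by(.data$graph_mode, .data$label, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$degree), se = sd(.data$degree) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$label, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.3, position = ggplot2::position_dodge(0.9)
    ) +
    ggplot2::facet_wrap(~graph_mode, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean nodal degree") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Edge t-statistic map of an NBS result
#'
#' Tile map of the signed edge-wise t statistics with the edges of
#' significant components outlined.
#'
#' @param object An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nbs_result
#' @export
autoplot.nbs_result <- function(object, ...) {
  labs <- rownames(object$edge_t)
  df <- tidyr::expand_grid(roi_i = labs, roi_j = labs)
  df$t <- as.vector(t(object$edge_t))
  sig <- object$components[
    object$components$fwer_p < object$config$component_alpha, ]
  sig_edges <- if (nrow(sig)) dplyr::bind_rows(sig$edges) else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$roi_j, levels = labs),
    y = factor(.data$roi_i, levels = rev(labs)),
    fill = .data$t
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "t") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(sig_edges)) {
    marks <- dplyr::bind_rows(
      sig_edges[, c("roi_i", "roi_j")],
      stats::setNames(sig_edges[, c("roi_j", "roi_i")],
                      c("roi_i", "roi_j"))
    )
    p <- p + ggplot2::geom_tile(
      data = marks, ggplot2::aes(
        x = factor(.data$roi_j, levels = labs),
        y = factor(.data$roi_i, levels = rev(labs))
      ),
      fill = NA, color = "black", linewidth = 0.4, inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
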