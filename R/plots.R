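# ggplot2 methods for the result objects

#' @export
autoplot.emg_heatmap <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (object$kind == "normalized")
      "activation" else "uV") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste(c(object$gesture_label,
                      if (!is.null(object$repetition))
                        paste("rep", object$repetition)), collapse = " "),
      x = "longitudinal column (proximal to distal)",
      y = "circumferential row (dorsal start)"
    )
}

#' @export
autoplot.similarity_matrix <- function(object, ...) {
  d <- expand.grid(item1 = object$labels, item2 = object$labels)
  d$r_squared <- as.vector(object$values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$item2, y = .data$item1,
                                  fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(R^2)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @export
autoplot.pca_dim <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = 100 * .data$cumulative_ve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 100 * object$ve_threshold,
                        linetype = "dashed", color = "blue") +
    ggplot2::labs(x = "number of principal components",
                  y = "cumulative variance explained (%)")
}

#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$k, y = 100 * .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$mean_accuracy - .data$sd_accuracy),
      ymax = 100 * (.data$mean_accuracy + .data$sd_accuracy)), width = 0.1) +
    ggplot2::labs(x = "number of gestures",
                  y = "offline classification accuracy (%)")
}
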