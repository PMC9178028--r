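#' Occlusal-view plot of a labelled arch
#'
#' Projects the mesh vertices into the occlusal plane (x, y) and colours
#' them by label; a quick visual check of segmentations and ground truth.
#'
#' @param mesh a [tri_mesh()].
#' @param labels a [label_map()].
#' @param sample_n optional cap on plotted vertices (plotting 10k+ points
#'   is slow in some devices).
#' @return a ggplot object.
#' @export
plot_labels <- function(mesh, labels, sample_n = 8000L) {
  df <- tibble::tibble(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                       label = factor(as.integer(labels)))
  if (nrow(df) > sample_n)
    df <- df[sort(sample.int(nrow(df), sample_n)), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "label",
                  title = "Occlusal view") +
    ggplot2::theme_minimal()
}

#' Training-curve plot for a fitted segmenter
#'
#' @param object a `dgcnn_model`.
#' @param ... unused.
#' @return a ggplot object with loss and point accuracy per epoch.
#' @export
autoplot.dgcnn_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log[, c("epoch", "loss", "accuracy")],
                            c("loss", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = sprintf("%d-class segmenter (%s preset)",
                                  object$params$n_classes,
                                  object$params$preset)) +
    ggplot2::theme_minimal()
}

#' Per-group measurement-error plot
#'
#' @param errors tibble from [summarize_errors()].
#' @return a ggplot object: mean error with 95% CI per tooth group.
#' @export
plot_error_summary <- function(errors) {
  ggplot2::ggplot(errors, ggplot2::aes(x = .data$group,
                                       y = .data$mean_error)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean error (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
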