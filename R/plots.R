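# ggplot2 displays for the result types.

#' Plot a tumor probability map as a tile heatmap
#'
#' @param pm `prob_map` from [probability_map()].
#' @returns A ggplot object (tile grid colored by tumor probability).
#' @export
plot_prob_map <- function(pm) {
  ts <- attr(pm, "tile_size")
  df <- tibble::as_tibble(pm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col0 + ts / 2,
                                   y = .data$row0 + ts / 2,
                                   fill = .data$prob)) +
    ggplot2::geom_tile(width = ts, height = ts) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1), name = "P(tumor)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (level-0 px)", y = "row (level-0 px)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_prob_map
#' @param object,... autoplot interface.
#' @method autoplot prob_map
#' @export
autoplot.prob_map <- function(object, ...) plot_prob_map(object)

#' @method autoplot her2_roc
#' @export
autoplot.her2_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @method autoplot her2_pr
#' @export
autoplot.her2_pr <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("PR (AP = %.3f)", object$ap)) +
    ggplot2::theme_minimal()
}

#' @method autoplot her2_confusion
#' @export
autoplot.her2_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_x_discrete(limits = object$classes) +
    ggplot2::labs(x = "Predicted", y = "Truth",
                  title = sprintf("Accuracy %.1f%%", 100 * object$accuracy)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Display an RGB image (patch or thumbnail) with ggplot2
#'
#' @param img [rgb_image] or bare array.
#' @returns A ggplot object.
#' @export
plot_rgb <- function(img) {
  p <- img_pixels(img)
  rast <- grDevices::as.raster(p / 255)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = ncol(p),
                               ymin = -nrow(p), ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, ncol(p)), ylim = c(-nrow(p), 0)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
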