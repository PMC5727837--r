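# ggplot2 visualization helpers.

map_to_tibble <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Plot a saliency map as a raster
#'
#' @param map Numeric matrix in [0, 1] or a `fused_saliency` object.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_saliency <- function(map, title = "saliency") {
  df <- map_to_tibble(saliency_values(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "saliency") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param x A `wce_roc` object from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wce_roc <- function(x, ...) {
  ggplot2::ggplot(x$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("pixel-wise ROC (AUC = %.3f)", x$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a localization result
#'
#' Shows the green-contour overlay of the predicted bleeding regions on the
#' input image.
#'
#' @param x A `wce_localization` object.
#' @param image The H x W x 3 input image the localization was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wce_localization <- function(x, image, ...) {
  ov <- overlay_mask(image, x$mask)
  df <- tibble::tibble(
    row = rep(seq_len(dim(ov)[1]), times = dim(ov)[2]),
    col = rep(seq_len(dim(ov)[2]), each = dim(ov)[1]),
    fill = grDevices::rgb(as.vector(ov[, , 1]), as.vector(ov[, , 2]),
                          as.vector(ov[, , 3]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "suspected bleeding regions", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data :=
NULL
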