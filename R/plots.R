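#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

mask_to_df <- function(mask, name) {
  tibble::tibble(
    row = rep(seq_len(mask$height), times = mask$width),
    col = rep(seq_len(mask$width), each = mask$height),
    foreground = as.vector(mask$values),
    mask = name)
}

#' Plot the three masks of a pipeline run
#'
#' Raster facets of the binarization, patch-classifier and combined masks.
#'
#' @param object A `prediction_bundle` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_bundle <- function(object, ...) {
  df <- dplyr::bind_rows(
    mask_to_df(object$bin_mask, "binarization"),
    mask_to_df(object$cnn_mask, "cnn"),
    mask_to_df(object$combined_mask, "combined"))
  df$mask <- factor(df$mask, c("binarization", "cnn", "combined"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$foreground)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey15",
                                          `TRUE` = "white")) +
    ggplot2::facet_wrap(~mask) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "foreground",
                  title = paste0("Pipeline masks - ", object$image_id))
}

#' Plot a training record
#'
#' Batch loss and validation error per epoch, with learning-rate drops
#' visible as dashed verticals.
#'
#' @param object A `flower_cnn_fit` from [train_cnn()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flower_cnn_fit <- function(object, ...) {
  rec <- tidyr::pivot_longer(object$record, c("loss", "val_error"),
                             names_to = "metric")
  drops <- object$record$step[c(FALSE, diff(object$record$lr) < 0)]
  p <- ggplot2::ggplot(rec, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Patch classifier training")
  if (length(drops) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = drops, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot benchmark score distributions
#'
#' Per-scene F1 and IoU of the three masks over the benchmark scene family.
#'
#' @param object A `flower_benchmark` from [run_flower_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flower_benchmark <- function(object, ...) {
  df <- tidyr::pivot_longer(object$results, c("f1", "iou"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$mask, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("Benchmark scores (%d scenes, %s light)",
                                  object$n_scenes,
                                  object$spec$illumination))
}
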