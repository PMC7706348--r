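#' Pixel-wise confusion counts between two masks
#'
#' Tallies true/false positives and negatives of a predicted mask against a
#' ground-truth mask of the same shape; the positive class is mask foreground.
#'
#' @param pred,truth [binary_mask()] objects of equal shape.
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "binary_mask"), inherits(truth, "binary_mask"))
  check_same_shape(pred, truth)
  p <- pred$values
  g <- truth$values
  tibble::tibble(
    tp = sum(p & g), fp = sum(p & !g),
    fn = sum(!p & g), tn = sum(!p & !g)
  )
}

#' Segmentation scores from confusion counts
#'
#' Computes the four pixel-level evaluation scores used throughout the
#' package:
#' \deqn{Recall = TP/(TP+FN),\; Precision = TP/(TP+FP),}
#' \deqn{F1 = 2TP/(2TP+FP+FN),\; IoU = TP/(TP+FP+FN).}
#' F1 (Dice) and IoU jointly summarize recall and precision and satisfy
#' `IoU = F1 / (2 - F1)`. A zero denominator yields `NA` for that score,
#' except the empty-vs-empty case (`tp + fp + fn == 0`, both masks empty)
#' where F1 and IoU are 1 by the perfect-agreement convention.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`, `tn` (one or
#'   more rows, e.g. from [confusion()]).
#' @return The input tibble with columns `recall`, `precision`, `f1`, `iou`
#'   appended.
#' @export
#' @examples
#' score_counts(data.frame(tp = 6, fp = 2, fn = 3, tn = 9))
score_counts <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  abort_if(any(unlist(counts[c("tp", "fp", "fn", "tn")]) < 0),
           "confusion counts must be non-negative")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(
    tibble::as_tibble(counts),
    recall    = safe_div(tp, tp + fn),
    precision = safe_div(tp, tp + fp),
    f1  = ifelse(tp + fp + fn == 0, 1, safe_div(2 * tp, 2 * tp + fp + fn)),
    iou = ifelse(tp + fp + fn == 0, 1, safe_div(tp, tp + fp + fn))
  )
}

#' Score a prediction mask (or all masks of a pipeline run) against truth
#'
#' `evaluate_mask()` scores one mask; `evaluate_bundle()` scores the three
#' masks of a [run_pipeline()] result — binarization, patch-CNN, and their
#' combination — against the same ground truth, one row per mask.
#'
#' @param pred A [binary_mask()].
#' @param bundle A `prediction_bundle` from [run_pipeline()].
#' @param truth A [binary_mask()] ground truth of matching shape.
#' @return A tibble with columns `mask`, `tp`, `fp`, `fn`, `tn`, `recall`,
#'   `precision`, `f1`, `iou`.
#' @export
evaluate_mask <- function(pred, truth) {
  dplyr::bind_cols(tibble::tibble(mask = pred$provenance),
                   score_counts(confusion(pred, truth)))
}

#' @rdname evaluate_mask
#' @export
evaluate_bundle <- function(bundle, truth) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  dplyr::bind_rows(
    evaluate_mask(bundle$bin_mask, truth),
    evaluate_mask(bundle$cnn_mask, truth),
    evaluate_mask(bundle$combined_mask, truth)
  )
}

#' Write an evaluation report as JSON
#'
#' @param report A tibble from [evaluate_mask()] or [evaluate_bundle()].
#' @param path Output JSON path. `NA` scores serialize as `null`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
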