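# Pixel-overlap evaluation: confusion counts and the five derived
# percentages (IoU, Dice, Recall, Specificity, Precision).

#' Confusion counts between a thresholded prediction and a binary mask
#'
#' @param pred probability map; @param target binary map; @param threshold
#'   binarization threshold in (0, 1).
#' @return list(tp, tn, fp, fn) in pixels.
#' @export
confusion_counts <- function(pred, target, threshold = 0.5) {
  check_pair(pred, target)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  p <- pred >= threshold
  y <- target > 0
  list(tp = sum(p & y), tn = sum(!p & !y), fp = sum(p & !y), fn = sum(!p & y))
}

ratio_pct <- function(num, den) if (den == 0) 100 else 100 * num / den

#' Segmentation metrics from confusion counts
#'
#' IoU = TP/(FP+TP+FN), Dice = 2TP/(FP+2TP+FN), Recall = TP/(TP+FN),
#' Specificity = TN/(TN+FP), Precision = TP/(FP+TP), as percentages.
#' A ratio whose denominator is zero (the class absent from both maps) is
#' reported as 100.
#'
#' @param cc list(tp, tn, fp, fn).
#' @return a `metrics_report` list of five percentages.
#' @export
metrics_from_counts <- function(cc) {
  structure(list(
    iou = ratio_pct(cc$tp, cc$fp + cc$tp + cc$fn),
    dice = ratio_pct(2 * cc$tp, cc$fp + 2 * cc$tp + cc$fn),
    recall = ratio_pct(cc$tp, cc$tp + cc$fn),
    specificity = ratio_pct(cc$tn, cc$tn + cc$fp),
    precision = ratio_pct(cc$tp, cc$fp + cc$tp),
    counts = cc
  ), class = "metrics_report")
}

#' Evaluate the five segmentation metrics
#'
#' Binarizes `pred` at `threshold`, accumulates confusion counts over all
#' pixels and returns the five percentages.
#'
#' @inheritParams confusion_counts
#' @return a `metrics_report`.
#' @export
evaluate_metrics <- function(pred, target, threshold = 0.5) {
  metrics_from_counts(confusion_counts(pred, target, threshold))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("IoU %.2f%%  Dice %.2f%%  Recall %.2f%%  Specificity %.2f%%  Precision %.2f%%\n",
              x$iou, x$dice, x$recall, x$specificity, x$precision))
  invisible(x)
}

metrics_row <- function(m, id = NA_character_) {
  data.frame(image = id, iou = m$iou, dice = m$dice, recall = m$recall,
             specificity = m$specificity, precision = m$precision,
             stringsAsFactors = FALSE)
}
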