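# ---------------------------------------------------------------------------
# Dice loss, confusion counts, Dice coefficient, accuracy.
# ---------------------------------------------------------------------------

#' Metric configuration
#'
#' @param eps Dice-loss smoothing constant (default `1e-5`)
#' @param threshold binarization threshold for probability maps; ties
#'   (`prob == threshold`) go to foreground
#' @param strict_empty if `TRUE`, [dice_loss()] returns 0 when prediction and
#'   target are both empty; the default `FALSE` follows the smoothed formula
#'   literally, which yields `1 - eps/(2*eps) = 0.5` in that case
#' @export
metric_config <- function(eps = 1e-5, threshold = 0.5, strict_empty = FALSE) {
  stopifnot(eps > 0, threshold > 0, threshold < 1)
  list(eps = eps, threshold = threshold, strict_empty = strict_empty)
}

#' Soft Dice loss
#'
#' `1 - (2*|X n Y| + eps) / (|X| + |Y| + 2*eps)` with the soft intersection
#' `sum(pred * target)`.  Differentiable in `pred`; see [dice_loss_grad()].
#'
#' @param pred probability map in `[0, 1]`
#' @param target binary map of the same shape
#' @param cfg a [metric_config()]
#' @return scalar loss in `[0, 1)`
#' @export
dice_loss <- function(pred, target, cfg = metric_config()) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target))) {
    stop("dice_loss: shape mismatch between pred and target")
  }
  inter <- sum(pred * target)
  size <- sum(pred) + sum(target)
  if (cfg$strict_empty && size == 0) return(0)
  1 - (2 * inter + cfg$eps) / (size + 2 * cfg$eps)
}

#' Gradient of the soft Dice loss with respect to the prediction
#' @inheritParams dice_loss
#' @return array of the same shape as `pred`
#' @export
dice_loss_grad <- function(pred, target, cfg = metric_config()) {
  inter <- sum(pred * target)
  size <- sum(pred) + sum(target)
  num <- 2 * inter + cfg$eps
  den <- size + 2 * cfg$eps
  g <- -(2 * target * den - num) / den^2
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}

#' Pixelwise confusion counts between two binary masks
#'
#' @param pred_bin,target binary arrays (values 0/1) of the same shape
#' @return object of class `fr_confusion`: list with integer `TP`, `FP`,
#'   `FN`, `TN`
#' @export
confusion_counts <- function(pred_bin, target) {
  if (!identical(dim(pred_bin) %||% length(pred_bin),
                 dim(target) %||% length(target))) {
    stop("confusion_counts: shape mismatch")
  }
  if (!all(pred_bin %in% c(0, 1)) || !all(target %in% c(0, 1))) {
    stop("confusion_counts: inputs must be strictly binary")
  }
  tp <- sum(pred_bin == 1 & target == 1)
  fp <- sum(pred_bin == 1 & target == 0)
  fn <- sum(pred_bin == 0 & target == 1)
  tn <- sum(pred_bin == 0 & target == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn), class = "fr_confusion")
}

#' Add two sets of confusion counts (micro-aggregation over images)
#' @param a,b `fr_confusion` objects
#' @export
confusion_add <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                 FN = a$FN + b$FN, TN = a$TN + b$TN), class = "fr_confusion")
}

#' Dice coefficient from confusion counts: `2TP / (2TP + FP + FN)`
#' @param c an `fr_confusion`
#' @export
dice_coefficient <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) {
    stop("dice_coefficient: undefined (no foreground in prediction or target)")
  }
  2 * c$TP / den
}

#' Pixel accuracy from confusion counts: `(TP + TN) / total`
#' @param c an `fr_confusion`
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$FP + c$FN + c$TN
  if (tot == 0) stop("accuracy: no pixels evaluated")
  (c$TP + c$TN) / tot
}

#' Binarize a probability map
#'
#' Pixels with `prob >= threshold` become foreground (ties to foreground).
#'
#' @param prob probability map in `[0, 1]`
#' @param cfg a [metric_config()]
#' @export
binarize <- function(prob, cfg = metric_config()) {
  out <- (prob >= cfg$threshold) * 1
  if (!is.null(dim(prob))) dim(out) <- dim(prob)
  out
}

#' Write a per-image + aggregate metrics table as CSV and JSON
#'
#' The aggregate row reports both the micro average (counts pooled over all
#' pixels of all images) and the mean of per-image scores.
#'
#' @param tab data frame with columns `id`, `dice`, `acc` and attributes as
#'   produced by [evaluate_model()]
#' @param path output stem; `.csv` and `.json` are appended
#' @export
write_metrics_table <- function(tab, path) {
  stem <- sub("\\.(csv|json)$", "", path)
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_image = tab,
         aggregate = attr(tab, "aggregate")),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(csv = paste0(stem, ".csv"), json = paste0(stem, ".json")))
}
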