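# Confusion-count based segmentation metrics (IoU, Dice, mIoU, precision,
# recall, F1) and min-max normalization. Metrics are micro-aggregated:
# counts are summed over all pixels (and, via add_confusion, over images)
# before any ratio is taken.

#' Per-class confusion counts
#'
#' One-vs-rest pixel counts per class: TP, FP, FN, TN. For each class
#' these sum to the total number of pixels.
#'
#' @param pred,gt Predicted and ground-truth label masks (integer matrices
#'   of identical shape, labels in `0..K-1`).
#' @param K Number of classes.
#' @return Object of class `confusion_counts`: a `K x 4` matrix with
#'   columns TP, FP, FN, TN and one row per class label (0-based order).
#' @export
confusion_counts <- function(pred, gt, K) {
  if (!all(dim(pred) == dim(gt)))
    stop("shape mismatch: pred is ", paste(dim(pred), collapse = "x"),
         ", gt is ", paste(dim(gt), collapse = "x"))
  pv <- as.integer(pred); gv <- as.integer(gt)
  if (any(pv >= K | gv >= K | pv < 0L | gv < 0L))
    stop("labels must lie in [0, K)")
  joint <- table(factor(pv, levels = 0:(K - 1L)),
                 factor(gv, levels = 0:(K - 1L)))
  total <- length(pv)
  tp <- diag(joint)
  fp <- rowSums(joint) - tp
  fn <- colSums(joint) - tp
  tn <- total - tp - fp - fn
  out <- cbind(TP = as.numeric(tp), FP = as.numeric(fp),
               FN = as.numeric(fn), TN = as.numeric(tn))
  rownames(out) <- 0:(K - 1L)
  structure(out, class = c("confusion_counts", class(out)))
}

#' Sum confusion counts across images
#'
#' @param ... `confusion_counts` objects with identical class sets.
#' @return Pooled `confusion_counts`.
#' @export
add_confusion <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) &&
      !inherits(lst[[1]], "confusion_counts")) lst <- lst[[1]]
  out <- Reduce(`+`, lapply(lst, unclass))
  structure(out, class = c("confusion_counts", class(out)))
}

#' Per-class IoU and Dice from confusion counts
#'
#' `IoU = TP / (TP + FP + FN)` and `Dice = 2 TP / (2 TP + FP + FN)`. A
#' class absent from both masks (TP = FP = FN = 0) gets `NA` and is
#' excluded from means; a class with error mass but no overlap gets 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return data.frame with columns `class`, `iou`, `dice`.
#' @export
iou_dice <- function(counts) {
  tp <- counts[, "TP"]; fp <- counts[, "FP"]; fn <- counts[, "FN"]
  denom_i <- tp + fp + fn
  iou <- ifelse(denom_i == 0, NA_real_, tp / denom_i)
  dice <- ifelse(denom_i == 0, NA_real_, 2 * tp / (2 * tp + fp + fn))
  data.frame(class = as.integer(rownames(counts)), iou = iou, dice = dice,
             row.names = NULL)
}

#' Mean IoU over a category set
#'
#' Averages per-class IoU over the configured categories (default: all
#' foreground classes, background label 0 excluded). Classes absent from
#' both masks are excluded from the mean.
#'
#' @param counts A [confusion_counts()] object.
#' @param categories Integer class labels to average over; `NULL` means
#'   all classes except background (label 0).
#' @return Scalar mean IoU.
#' @export
miou <- function(counts, categories = NULL) {
  id <- iou_dice(counts)
  if (is.null(categories)) categories <- setdiff(id$class, 0L)
  sel <- id$iou[id$class %in% categories]
  if (all(is.na(sel))) return(NA_real_)
  mean(sel, na.rm = TRUE)
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Degenerate 0/0
#' ratios resolve to 0 when any error mass exists and to `NA` (class
#' absent everywhere) otherwise; with TP = 0 and FP + FN > 0, F1 is 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[, "TP"]; fp <- counts[, "FP"]; fn <- counts[, "FN"]
  absent <- (tp + fp + fn) == 0
  precision <- ifelse(tp + fp == 0, ifelse(absent, NA_real_, 0),
                      tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, ifelse(absent, NA_real_, 0),
                   tp / (tp + fn))
  f1 <- ifelse(absent, NA_real_,
               ifelse(tp == 0, 0,
                      2 * precision * recall / (precision + recall)))
  data.frame(class = as.integer(rownames(counts)), precision = precision,
             recall = recall, f1 = f1, row.names = NULL)
}

#' All segmentation metrics for a prediction
#'
#' @param pred,gt Label masks.
#' @param K Number of classes.
#' @param categories mIoU category set (see [miou()]).
#' @return List with `per_class` (data.frame), `miou`, `mean_dice`,
#'   `mean_f1` over the category set.
#' @export
seg_metrics <- function(pred, gt, K, categories = NULL) {
  counts <- confusion_counts(pred, gt, K)
  id <- iou_dice(counts)
  prf <- precision_recall_f1(counts)
  per_class <- merge(id, prf, by = "class")
  if (is.null(categories)) categories <- setdiff(id$class, 0L)
  sel <- per_class$class %in% categories
  list(per_class = per_class,
       miou = mean(per_class$iou[sel], na.rm = TRUE),
       mean_dice = mean(per_class$dice[sel], na.rm = TRUE),
       mean_f1 = mean(per_class$f1[sel], na.rm = TRUE),
       counts = counts)
}

#' Min-max normalization
#'
#' Rescales a vector to `[0, 1]` by `(x - min) / (max - min)`.
#'
#' @param x Numeric vector of length >= 1.
#' @return Normalized vector; the minimum maps to 0 and the maximum to 1.
#' @export
minmax_normalize <- function(x) {
  stopifnot(length(x) >= 1L)
  lo <- min(x); hi <- max(x)
  if (hi == lo)
    stop("min-max scaling undefined: all values equal (", lo, ")")
  (x - lo) / (hi - lo)
}
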