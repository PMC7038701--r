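# Segmentation evaluation: confusion matrix and the four standard metrics
# (pixel accuracy, mean per-class accuracy, mean IoU, frequency-weighted
# IoU). Conventions: counts n_ij = pixels of true class i predicted as j,
# t_i = row sums; classes absent from the ground truth (t_i = 0) are
# excluded from the ma / mIU averages; metrics over a test set pool the
# confusion matrices across images before evaluating.

#' Confusion matrix of a predicted mask against ground truth
#'
#' @param pred,gt integer label matrices of identical size with labels in
#'   `[0, n_classes)`.
#' @param n_classes number of classes (`>= 2`).
#' @return a `seg_confusion`: `n_classes`-square integer matrix, entry
#'   `[i, j]` counting pixels of true class `i - 1` predicted as `j - 1`.
#' @examples
#' gt <- matrix(c(0L, 0L, 1L, 1L), 2); pr <- matrix(c(0L, 1L, 1L, 1L), 2)
#' seg_confusion(pr, gt, 2)
#' @export
seg_confusion <- function(pred, gt, n_classes) {
  check_label_mask(pred, "pred")
  check_label_mask(gt, "gt")
  if (!all(dim(pred) == dim(gt)))
    stop_invalid("pred and gt must have identical dimensions")
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L)
    stop_invalid("n_classes must be an integer >= 2")
  if (max(pred) >= n_classes || max(gt) >= n_classes)
    stop_invalid("labels out of range [0, n_classes)")
  idx <- as.integer(gt) + n_classes * as.integer(pred) + 1L
  cm <- matrix(tabulate(idx, nbins = n_classes^2), n_classes, n_classes)
  dimnames(cm) <- list(true = 0:(n_classes - 1L), pred = 0:(n_classes - 1L))
  structure(cm, class = c("seg_confusion", class(cm)))
}

#' Sum confusion matrices over a set of images
#'
#' @param ... `seg_confusion` matrices (or a single list of them).
#' @return the pooled `seg_confusion`.
#' @export
pool_confusions <- function(...) {
  cms <- list(...)
  if (length(cms) == 1L && is.list(cms[[1L]]) && !is.matrix(cms[[1L]]))
    cms <- cms[[1L]]
  out <- Reduce(`+`, cms)
  structure(out, class = c("seg_confusion", "matrix", "array"))
}

#' Segmentation metrics from a confusion matrix
#'
#' Computes, with `n_ij` the confusion counts and `t_i` the row sums:
#' pixel accuracy `pa = sum(n_ii) / sum(t_i)`; mean accuracy
#' `ma = mean(n_ii / t_i)`; per-class IoU
#' `n_ii / (t_i + sum_j n_ji - n_ii)` with mean `miou`; and the
#' frequency-weighted `fwiou = sum(t_i * iou_i) / sum(t_k)`. Averages run
#' over classes present in the ground truth.
#'
#' @param cm a `seg_confusion` (or any square count matrix).
#' @return a `seg_metrics`: list with `pa`, `ma`, `miou`, `fwiou`,
#'   `per_class_iou` (NA for absent classes) and `n_classes`.
#' @examples
#' cm <- matrix(c(3, 2, 1, 4), 2)  # rows = truth
#' seg_evaluate(cm)$pa             # 0.7
#' @export
seg_evaluate <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop_invalid("cm must be a square matrix")
  if (anyNA(cm) || any(cm < 0))
    stop_invalid("cm must contain non-negative counts")
  if (sum(cm) == 0)
    stop_invalid("cm has no counts; nothing was evaluated")
  ti <- rowSums(cm)
  nii <- diag(cm)
  present <- ti > 0
  denom <- ti + colSums(cm) - nii
  iou <- ifelse(present, nii / denom, NA_real_)
  structure(list(
    pa = sum(nii) / sum(ti),
    ma = mean(nii[present] / ti[present]),
    miou = mean(iou[present]),
    fwiou = sum(ti[present] * iou[present]) / sum(ti),
    per_class_iou = iou,
    n_classes = nrow(cm)
  ), class = "seg_metrics")
}

#' Evaluate predicted masks against ground truth
#'
#' Convenience wrapper: builds the (pooled) confusion matrix from one mask
#' pair or parallel lists of pairs, then calls [seg_evaluate()].
#'
#' @param pred,gt label matrices, or lists of label matrices.
#' @param n_classes number of classes.
#' @return a `seg_metrics`.
#' @export
seg_metrics <- function(pred, gt, n_classes) {
  if (is.list(pred)) {
    stopifnot(is.list(gt), length(pred) == length(gt))
    cms <- Map(seg_confusion, pred, gt, MoreArgs = list(n_classes = n_classes))
    return(seg_evaluate(pool_confusions(cms)))
  }
  seg_evaluate(seg_confusion(pred, gt, n_classes))
}

#' @export
print.seg_metrics <- function(x, digits = 4, ...) {
  cat("segmentation metrics (", x$n_classes, " classes):\n", sep = "")
  cat(sprintf("  pa     %.*f\n  ma     %.*f\n  miou   %.*f\n  fwiou  %.*f\n",
              digits, x$pa, digits, x$ma, digits, x$miou, digits, x$fwiou))
  invisible(x)
}

#' @export
as.data.frame.seg_metrics <- function(x, ...) {
  data.frame(metric = c("pa", "ma", "miou", "fwiou"),
             value = c(x$pa, x$ma, x$miou, x$fwiou))
}
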