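#' Dice coefficient between two binary masks
#'
#' `2|X n Y| / (|X| + |Y|)`. When both masks are empty the score is undefined
#' and `NA` is returned (such labels are excluded from class means by
#' [evaluate_segmentation()]).
#'
#' @param pred,truth Logical matrices of the same shape.
#' @return Dice in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dice <- function(pred, truth) {
  check_same_shape(pred, truth)
  np <- sum(pred); nt <- sum(truth)
  if (np + nt == 0L) return(NA_real_)
  2 * sum(pred & truth) / (np + nt)
}

#' Intersection over union (Jaccard index) between two binary masks
#'
#' `|X n Y| / |X u Y|`; `NA` when both masks are empty.
#'
#' @inheritParams dice
#' @return IoU in `[0, 1]`, or `NA` if both masks are empty.
#' @export
iou <- function(pred, truth) {
  check_same_shape(pred, truth)
  u <- sum(pred | truth)
  if (u == 0L) return(NA_real_)
  sum(pred & truth) / u
}

check_same_shape <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(truth), collapse = "x"))
  }
  invisible(TRUE)
}

#' Per-label and class-averaged segmentation scores
#'
#' Computes Dice and IoU for each requested label and their class means
#' (mDice, mIoU). A label that is empty in both prediction and truth carries
#' no information and is excluded from the means (the class count `n` counts
#' only scored labels); a label empty in exactly one map scores 0. Background
#' is never scored.
#'
#' @param pred,truth [label_map()]s with identical shape and scheme.
#' @param labels Character vector of label names to score; defaults to all 15.
#' @return A `segmentation_scores` object: `per_label` (data.frame with
#'   columns `label`, `dice`, `iou`; `NA` where unscored), `mdice`, `miou`,
#'   `n_classes_scored`.
#' @export
evaluate_segmentation <- function(pred, truth, labels = names(pred$scheme)) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  check_same_shape(pred$grid, truth$grid)
  if (!identical(unname(pred$scheme), unname(truth$scheme)) ||
      !identical(tolower(names(pred$scheme)), tolower(names(truth$scheme)))) {
    stop("prediction and truth use different label schemes")
  }
  if (!length(labels)) stop("no labels requested for evaluation")

  per <- lapply(labels, function(nm) {
    pm <- extract_mask(pred, nm)
    tm <- extract_mask(truth, nm)
    c(dice = dice(pm, tm), iou = iou(pm, tm))
  })
  per <- do.call(rbind, per)
  out <- data.frame(label = labels, dice = per[, "dice"], iou = per[, "iou"],
                    stringsAsFactors = FALSE, row.names = NULL)
  scored <- !is.na(out$dice)
  structure(list(per_label = out,
                 mdice = mean(out$dice[scored]),
                 miou = mean(out$iou[scored]),
                 n_classes_scored = sum(scored)),
            class = "segmentation_scores")
}

#' @export
print.segmentation_scores <- function(x, ...) {
  cat(sprintf("<segmentation_scores> %d classes scored, mDice %.4f, mIoU %.4f\n",
              x$n_classes_scored, x$mdice, x$miou))
  df <- x$per_label
  df$dice <- sprintf("%.4f", df$dice)
  df$iou <- sprintf("%.4f", df$iou)
  print(df, row.names = FALSE)
  invisible(x)
}
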