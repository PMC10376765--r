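# Evaluation metrics: confusion-matrix summaries with Wilson intervals,
# ROC/AUC by trapezoidal integration, and detection AP with greedy
# confidence-ordered matching.

#' Classification metrics from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @param conf_level Level for the Wilson score intervals on sensitivity and
#'   specificity.
#' @return List with accuracy, sensitivity, specificity, precision, recall,
#'   f1, and Wilson intervals `sensitivity_ci` / `specificity_ci`. Ratios with
#'   a zero denominator are `NaN` (with a note), never silently 0.
#' @export
#' @examples
#' classification_metrics(50, 10, 80, 20)$sensitivity  # 0.714...
classification_metrics <- function(tp, fp, tn, fn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      message("undefined ", what, " (zero denominator); reported as NaN")
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity/recall")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  acc <- safe_div(tp + tn, tp + fp + tn + fn, "accuracy")
  f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) NaN else
    2 * prec * sens / (prec + sens)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       precision = prec, recall = sens, f1 = f1,
       sensitivity_ci = wilson_ci(tp, tp + fn, conf_level),
       specificity_ci = wilson_ci(tn, tn + fp, conf_level))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes; `n` trials; `conf_level` coverage.
#' @param n,conf_level See above.
#' @return Length-2 vector (lower, upper), or `c(NaN, NaN)` when `n == 0`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  if (n == 0) return(c(NaN, NaN))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (descending) and
#' integrates the ROC curve with the trapezoidal rule; tied scores enter at a
#' single threshold, which averages over ties and makes the AUC equal to the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1), both classes present.
#' @return Object of class `fg_roc`: list with `thresholds` (descending),
#'   `tpr`, `fpr` (each starting at 0,0 and ending at 1,1) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]; fpc <- cumsum(1 - y)[last]
  tpr <- c(0, tp / np); fpr <- c(0, fpc / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auc = auc), class = "fg_roc")
}

# intersection-over-union of two boxes (x_min, y_min, x_max, y_max)
box_iou <- function(a, b) {
  iw <- pmax(0, pmin(a[3], b[3]) - pmax(a[1], b[1]))
  ih <- pmax(0, pmin(a[4], b[4]) - pmax(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Detection average precision (AP) and mAP
#'
#' Greedy confidence-ordered matching: predictions are ranked by confidence
#' (ties broken by lowest `x_min`), each prediction matches at most one
#' still-unmatched ground-truth box of its class in its image with IoU at or
#' above the threshold; duplicates count as false positives. AP is the area
#' under the all-points interpolated precision-recall curve, and mAP averages
#' AP over classes present in the ground truth. Classes predicted but absent
#' from the ground truth have an undefined AP and are excluded with a note.
#'
#' @param predictions data.frame with columns `image`, `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `confidence`.
#' @param ground_truth data.frame with the same box columns (no confidence).
#' @param iou_threshold Matching threshold, default 0.5.
#' @return List with `per_class` (data.frame class/ap/recall/precision/n_gt)
#'   and `map`.
#' @export
detection_map <- function(predictions, ground_truth, iou_threshold = 0.5) {
  gt_classes <- unique(ground_truth$class)
  extra <- setdiff(unique(predictions$class), gt_classes)
  if (length(extra))
    message("classes absent from ground truth excluded from mAP: ",
            paste(extra, collapse = ", "))
  rows <- lapply(gt_classes, function(cl) {
    gt <- ground_truth[ground_truth$class == cl, , drop = FALSE]
    pr <- predictions[predictions$class == cl, , drop = FALSE]
    n_gt <- nrow(gt)
    if (nrow(pr) == 0)
      return(data.frame(class = cl, ap = 0, recall = 0, precision = NaN,
                        n_gt = n_gt))
    pr <- pr[order(-pr$confidence, pr$x_min), , drop = FALSE]
    used <- rep(FALSE, n_gt)
    tp <- numeric(nrow(pr))
    for (i in seq_len(nrow(pr))) {
      cand <- which(gt$image == pr$image[i] & !used)
      if (!length(cand)) next
      ious <- vapply(cand, function(j)
        box_iou(as.numeric(pr[i, c("x_min", "y_min", "x_max", "y_max")]),
                as.numeric(gt[j, c("x_min", "y_min", "x_max", "y_max")])),
        numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_threshold) {
        tp[i] <- 1
        used[cand[best]] <- TRUE
      }
    }
    ctp <- cumsum(tp); cfp <- cumsum(1 - tp)
    rec <- ctp / n_gt
    prec <- ctp / (ctp + cfp)
    # all-points interpolation: precision envelope from the right
    penv <- rev(cummax(rev(prec)))
    ap <- sum(diff(c(0, rec)) * penv)
    data.frame(class = cl, ap = ap, recall = rec[length(rec)],
               precision = prec[length(prec)], n_gt = n_gt)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, map = mean(per_class$ap))
}
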