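#' Greedy IoU matching of predictions against ground truth
#'
#' Predictions are processed in descending score order; each is matched to
#' the still-unmatched ground-truth box of highest IoU provided that IoU
#' reaches the threshold (the standard detection-benchmark protocol).
#' Matching is one-to-one: `TP = |matches|`, `FP = predictions - TP`,
#' `FN = ground truth - TP`.
#'
#' @param predictions scored box data.frame.
#' @param ground_truth box data.frame.
#' @param iou_threshold minimum IoU for a match.
#' @return A list with `true_positives`, `false_positives`,
#'   `false_negatives`, `matches` (data.frame `pred_idx, gt_idx, iou` in
#'   original row indices) and `pred_order` / `pred_is_tp` giving, for the
#'   predictions sorted by descending score, their original index and TP
#'   flag.
#' @export
match_detections <- function(predictions, ground_truth, iou_threshold = 0.5) {
  np <- nrow(predictions); ng <- nrow(ground_truth)
  sc <- if (np) ifelse(is.na(predictions$score), 1, predictions$score) else numeric()
  ord <- order(-sc)
  iou <- box_iou(predictions, ground_truth)
  gt_taken <- logical(ng)
  is_tp <- logical(np)
  matches <- list()
  for (p in ord) {
    if (!ng) break
    cand <- iou[p, ]
    cand[gt_taken] <- -1
    g <- which.max(cand)
    if (length(g) && cand[g] >= iou_threshold && cand[g] > 0) {
      gt_taken[g] <- TRUE
      is_tp[p] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(pred_idx = p, gt_idx = g, iou = iou[p, g])
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(pred_idx = integer(), gt_idx = integer(), iou = numeric())
  list(true_positives = sum(is_tp),
       false_positives = np - sum(is_tp),
       false_negatives = ng - sum(is_tp),
       matches = matches,
       pred_order = ord,
       pred_is_tp = is_tp[ord])
}

#' Average precision at a fixed IoU threshold
#'
#' Area under the precision-recall curve of the score-ranked predictions,
#' pooled over images, with all-points interpolation (the precision
#' envelope). `interpolation = "points101"` instead averages the
#' interpolated precision over the 101 recall points 0, 0.01, ..., 1
#' (COCO-style).
#'
#' @param predictions,ground_truth either single box data.frames (one
#'   image) or named lists of box data.frames keyed by image id.
#' @param iou_threshold IoU threshold for a true positive.
#' @param interpolation `"all"` (precision envelope, default) or
#'   `"points101"`.
#' @return AP in `[0, 1]`; 0 when there are no predictions, `NA` when there
#'   is no ground truth.
#' @export
average_precision <- function(predictions, ground_truth, iou_threshold = 0.5,
                              interpolation = c("all", "points101")) {
  interpolation <- match.arg(interpolation)
  pr <- pr_points(predictions, ground_truth, iou_threshold)
  if (is.null(pr)) return(NA_real_)
  if (!nrow(pr)) return(0)
  if (interpolation == "all") {
    env <- rev(cummax(rev(pr$precision)))
    sum((pr$recall - c(0, head(pr$recall, -1))) * env)
  } else {
    grid <- seq(0, 1, by = 0.01)
    interp <- vapply(grid, function(r) {
      ok <- pr$recall >= r
      if (any(ok)) max(pr$precision[ok]) else 0
    }, numeric(1))
    mean(interp)
  }
}

# Pooled precision-recall points over images; NULL when no ground truth,
# 0-row data.frame when no predictions.
pr_points <- function(predictions, ground_truth, iou_threshold) {
  if (is.data.frame(predictions)) predictions <- list(img = predictions)
  if (is.data.frame(ground_truth)) ground_truth <- list(img = ground_truth)
  ids <- union(names(predictions), names(ground_truth))
  n_gt <- 0L; scores <- numeric(); tps <- logical()
  for (id in ids) {
    p <- predictions[[id]]; g <- ground_truth[[id]]
    if (is.null(p)) p <- empty_boxes()
    if (is.null(g)) g <- empty_boxes()
    n_gt <- n_gt + nrow(g)
    if (nrow(p)) {
      m <- match_detections(p, g, iou_threshold)
      sc <- ifelse(is.na(p$score), 1, p$score)
      scores <- c(scores, sc[m$pred_order])
      tps <- c(tps, m$pred_is_tp)
    }
  }
  if (n_gt == 0L) return(NULL)
  if (!length(scores))
    return(data.frame(recall = numeric(), precision = numeric(),
                      score = numeric()))
  ord <- order(-scores)
  tp_cum <- cumsum(tps[ord])
  n <- seq_along(tp_cum)
  data.frame(recall = tp_cum / n_gt, precision = tp_cum / n,
             score = scores[ord])
}

#' Mean average precision over IoU thresholds
#'
#' With a single category (stomata), mAP per threshold equals the pooled AP
#' of that category; the category axis is kept only for format
#' compatibility.
#'
#' @inheritParams average_precision
#' @param thresholds IoU thresholds to evaluate.
#' @return Named numeric vector of mAP values, one per threshold.
#' @examples
#' gt <- boxes_df(c(10, 60), c(10, 10), c(40, 90), c(30, 30))
#' pred <- gt; pred$score <- c(0.9, 0.8)
#' mean_ap(pred, gt, thresholds = c(0.3, 0.5))
#' @export
mean_ap <- function(predictions, ground_truth, thresholds = c(0.3, 0.5),
                    interpolation = c("all", "points101")) {
  interpolation <- match.arg(interpolation)
  out <- vapply(thresholds, function(th)
    average_precision(predictions, ground_truth, th, interpolation),
    numeric(1))
  names(out) <- paste0("mAP@", format(thresholds))
  out
}

#' Full detection evaluation report
#'
#' Matching counts, AP and precision-recall points at each IoU threshold.
#'
#' @inheritParams mean_ap
#' @return A list of class `"stoma_eval"` with a `summary` data.frame
#'   (threshold, AP, TP, FP, FN) and per-threshold PR curves in
#'   `pr_curves`.
#' @export
evaluate_detections <- function(predictions, ground_truth,
                                thresholds = c(0.3, 0.5),
                                interpolation = c("all", "points101")) {
  interpolation <- match.arg(interpolation)
  if (is.data.frame(predictions)) predictions <- list(img = predictions)
  if (is.data.frame(ground_truth)) ground_truth <- list(img = ground_truth)
  rows <- list(); curves <- list()
  for (th in thresholds) {
    tp <- fp <- fn <- 0L
    ids <- union(names(predictions), names(ground_truth))
    for (id in ids) {
      p <- predictions[[id]]; g <- ground_truth[[id]]
      if (is.null(p)) p <- empty_boxes()
      if (is.null(g)) g <- empty_boxes()
      m <- match_detections(p, g, th)
      tp <- tp + m$true_positives; fp <- fp + m$false_positives
      fn <- fn + m$false_negatives
    }
    ap <- average_precision(predictions, ground_truth, th, interpolation)
    rows[[length(rows) + 1L]] <-
      data.frame(iou_threshold = th, ap = ap, tp = tp, fp = fp, fn = fn)
    curves[[format(th)]] <- pr_points(predictions, ground_truth, th)
  }
  structure(list(summary = do.call(rbind, rows), pr_curves = curves),
            class = "stoma_eval")
}

#' @export
print.stoma_eval <- function(x, ...) {
  cat("Detection evaluation\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Percentage error of an automated count or density
#'
#' `100 * |auto - manual| / manual`, the error rate used to compare
#' automated stomatal density estimates with manual counts.
#'
#' @param auto automated estimate.
#' @param manual manual reference (> 0).
#' @return Error in percent.
#' @examples
#' count_error_rate(16.8, 16.2)  # 3.70
#' @export
count_error_rate <- function(auto, manual) {
  stopifnot(all(manual > 0))
  100 * abs(auto - manual) / manual
}
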