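#' Intersection over union of two boxes
#'
#' Areas use continuous coordinates, `(x_max - x_min) * (y_max - y_min)`.
#' Disjoint boxes score 0; identical boxes score 1.
#'
#' @param a,b One-row box tables (or the first rows are used).
#' @return IOU in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(a, b) {
  ax1 <- a$x_min[1]; ay1 <- a$y_min[1]; ax2 <- a$x_max[1]; ay2 <- a$y_max[1]
  bx1 <- b$x_min[1]; by1 <- b$y_min[1]; bx2 <- b$x_max[1]; by2 <- b$y_max[1]
  area_a <- (ax2 - ax1) * (ay2 - ay1)
  area_b <- (bx2 - bx1) * (by2 - by1)
  if (area_a <= 0 || area_b <= 0) stop("degenerate (zero-area) bounding box")
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

## IOU of one box against every row of a box table (vectorized).
iou_vec <- function(a, boxes) {
  if (nrow(boxes) == 0) return(numeric())
  ax1 <- a$x_min[1]; ay1 <- a$y_min[1]; ax2 <- a$x_max[1]; ay2 <- a$y_max[1]
  area_a <- (ax2 - ax1) * (ay2 - ay1)
  area_b <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  if (area_a <= 0 || any(area_b <= 0)) stop("degenerate (zero-area) bounding box")
  iw <- pmin(ax2, boxes$x_max) - pmax(ax1, boxes$x_min)
  ih <- pmin(ay2, boxes$y_max) - pmax(ay1, boxes$y_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / (area_a + area_b - inter)
}

#' Greedily match detections to ground-truth boxes
#'
#' Detections are processed in order of descending score (ties keep input
#' order). Each detection is paired with the not-yet-matched ground truth of
#' highest IOU, provided that IOU is at least `iou_threshold` (IOU >= 0.5 by
#' default defines a correct detection); otherwise it is a false positive.
#' Ground truths left unmatched are false negatives.
#'
#' @param detections Box table with a `score` column.
#' @param ground_truths Box table.
#' @param iou_threshold Minimum IOU for a correct detection.
#' @return An object of class `match_result`: list with `pairs` (data frame
#'   of `det`, `gt`, `iou` indices into the inputs), `fp_indices`,
#'   `fn_indices`.
#' @export
match_detections <- function(detections, ground_truths, iou_threshold = 0.5) {
  n_det <- nrow(detections)
  n_gt <- nrow(ground_truths)
  order_det <- if (n_det > 0) {
    order(-detections$score, seq_len(n_det))
  } else integer()
  gt_free <- rep(TRUE, n_gt)
  pairs <- vector("list", n_det)
  fp <- integer()
  for (i in order_det) {
    ious <- iou_vec(detections[i, ], ground_truths)
    ious[!gt_free] <- -Inf
    if (n_gt > 0 && max(ious) >= iou_threshold) {
      j <- which.max(ious)
      gt_free[j] <- FALSE
      pairs[[i]] <- data.frame(det = i, gt = j, iou = ious[j])
    } else {
      fp <- c(fp, i)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(det = integer(), gt = integer(), iou = numeric())
  }
  structure(
    list(pairs = pairs, fp_indices = sort(fp),
         fn_indices = which(gt_free)),
    class = "match_result"
  )
}

#' Precision, recall and F1 from match counts
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F1 the harmonic mean
#' of the two. A metric with a zero denominator is undefined and returned as
#' `NA` (never coerced to 0 or 1); F1 is `NA` whenever precision or recall is.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named list with `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(5944, 617, 375) # recall 0.94, f1 0.92 at 2 dp
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (!is.na(precision) && !is.na(recall)) {
    0
  } else {
    NA_real_
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' All-point-interpolation average precision
#'
#' Computes the area under the precision-recall curve of a ranked detection
#' list: cumulative precision and recall are computed down the ranking, the
#' precision curve is made monotone non-increasing (each point takes the
#' maximum precision at equal or greater recall), and AP is the exact area
#' under that envelope.
#'
#' @param tp_flags Logical vector, `TRUE` where the ranked detection is a
#'   true positive; must already be sorted by descending score.
#' @param n_ground_truth Total number of ground-truth objects (>= 1).
#' @return AP in `[0, 1]`.
#' @examples
#' average_precision(rep(TRUE, 102), 103) # 102/103, prints as 99%
#' @export
average_precision <- function(tp_flags, n_ground_truth) {
  if (n_ground_truth < 1) stop("n_ground_truth must be at least 1")
  tp_flags <- as.logical(tp_flags)
  if (length(tp_flags) == 0) return(0)
  cum_tp <- cumsum(tp_flags)
  precision <- cum_tp / seq_along(tp_flags)
  recall <- cum_tp / n_ground_truth
  envelope <- rev(cummax(rev(precision)))
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * envelope)
}

#' Mean centre error of matched boxes
#'
#' The Euclidean distance in pixels between the centres of each matched
#' detection/ground-truth pair, averaged over the matches of the transect.
#' Unmatched boxes do not contribute. With no matched pair the error is
#' undefined (`NA`).
#'
#' @param match A [match_detections()] result.
#' @param detections,ground_truths The box tables that were matched.
#' @return Mean distance in pixels, or `NA` if no pair matched.
#' @export
mean_center_error <- function(match, detections, ground_truths) {
  stopifnot(inherits(match, "match_result"))
  if (nrow(match$pairs) == 0) return(NA_real_)
  dc <- bbox_centers(detections[match$pairs$det, , drop = FALSE])
  gc <- bbox_centers(ground_truths[match$pairs$gt, , drop = FALSE])
  mean(sqrt(rowSums((dc - gc)^2)))
}

#' Signed percentage difference in object counts
#'
#' `(n_detected - n_ground_truth) / n_ground_truth * 100`: positive when the
#' detector over-counts.
#'
#' @param n_detected,n_ground_truth Counts; `n_ground_truth` must be >= 1.
#' @return Signed percentage.
#' @export
count_difference_pct <- function(n_detected, n_ground_truth) {
  if (n_ground_truth < 1) stop("n_ground_truth must be at least 1")
  (n_detected - n_ground_truth) / n_ground_truth * 100
}

#' Evaluate one transect
#'
#' @param detections Box table with scores.
#' @param ground_truths Box table.
#' @param iou_threshold Minimum IOU for a correct detection.
#' @return An object of class `transect_eval`: counts, precision/recall/F1
#'   (`NA` where undefined), `mce`, `count_diff_pct` (`NA` with no ground
#'   truth), and the underlying `match`.
#' @export
evaluate_transect <- function(detections, ground_truths, iou_threshold = 0.5) {
  m <- match_detections(detections, ground_truths, iou_threshold)
  tp <- nrow(m$pairs)
  fp <- length(m$fp_indices)
  fn <- length(m$fn_indices)
  prf <- precision_recall_f1(tp, fp, fn)
  structure(
    c(list(tp = tp, fp = fp, fn = fn), prf,
      list(mce = mean_center_error(m, detections, ground_truths),
           count_diff_pct = if (nrow(ground_truths) >= 1) {
             count_difference_pct(nrow(detections), nrow(ground_truths))
           } else NA_real_,
           match = m)),
    class = "transect_eval"
  )
}

#' @export
print.transect_eval <- function(x, ...) {
  cat(sprintf("<transect_eval> TP %d FP %d FN %d | P %.3f R %.3f F1 %.3f | MCE %.2f px\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$mce))
  invisible(x)
}

## Median and 5th/95th percentile summary of per-transect values, NA-safe.
summary_stats <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(list(mean = NA_real_, median = NA_real_,
                q05 = NA_real_, q95 = NA_real_))
  }
  q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
  list(mean = mean(v), median = stats::median(v), q05 = q[1], q95 = q[2])
}

#' Evaluate a detection set over many transects
#'
#' Matches detections to ground truths transect by transect, then reports
#' both pooled metrics (counts summed over transects before computing
#' precision/recall/F1, plus AP over the pooled score ranking) and
#' per-transect macro statistics (unweighted mean, median and 5th/95th
#' percentiles of each per-transect metric). Pooled and macro values answer
#' different questions and generally differ; both are labelled explicitly.
#' Swapping the roles of the two box sets (e.g. to compare two labellers)
#' swaps FP with FN and precision with recall.
#'
#' @param detections Named list of box tables (with scores), one per
#'   transect.
#' @param ground_truths Named list of box tables with the same names.
#' @param iou_threshold Minimum IOU for a correct detection.
#' @return An object of class `dataset_eval`: pooled counts and metrics,
#'   `ap`, macro summaries, and the per-transect `transect_eval` list.
#' @export
evaluate_dataset <- function(detections, ground_truths, iou_threshold = 0.5) {
  ids_d <- names(detections)
  ids_g <- names(ground_truths)
  if (is.null(ids_d) || is.null(ids_g)) {
    stop("detections and ground_truths must be named lists keyed by transect id")
  }
  bad <- union(setdiff(ids_d, ids_g), setdiff(ids_g, ids_d))
  if (length(bad) > 0) {
    stop("transect ids do not align between detections and ground truths: ",
         paste(bad, collapse = ", "))
  }
  per <- lapply(ids_d, function(id) {
    evaluate_transect(detections[[id]], ground_truths[[id]], iou_threshold)
  })
  names(per) <- ids_d

  tp <- sum(vapply(per, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(per, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(per, `[[`, numeric(1), "fn"))
  pooled <- precision_recall_f1(tp, fp, fn)

  # pooled AP: every detection, ranked by score across transects, flagged TP
  # according to its within-transect match
  flags <- do.call(rbind, lapply(ids_d, function(id) {
    d <- detections[[id]]
    if (nrow(d) == 0) return(NULL)
    data.frame(score = d$score,
               tp = seq_len(nrow(d)) %in% per[[id]]$match$pairs$det)
  }))
  n_gt_total <- tp + fn
  ap <- if (is.null(flags) || n_gt_total == 0) {
    NA_real_
  } else {
    flags <- flags[order(-flags$score), , drop = FALSE]
    average_precision(flags$tp, n_gt_total)
  }

  metric <- function(name) vapply(per, `[[`, numeric(1), name)
  structure(
    list(n_transects = length(per),
         pooled = c(list(tp = tp, fp = fp, fn = fn), pooled),
         ap = ap,
         macro = list(precision = summary_stats(metric("precision")),
                      recall = summary_stats(metric("recall")),
                      f1 = summary_stats(metric("f1")),
                      mce = summary_stats(metric("mce")),
                      count_diff_pct = summary_stats(metric("count_diff_pct"))),
         per_transect = per),
    class = "dataset_eval"
  )
}

#' @export
print.dataset_eval <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<dataset_eval> %d transect(s)\n", x$n_transects))
  cat(sprintf("  pooled: TP %d FP %d FN %d | P %.3f R %.3f F1 %.3f | AP %.3f\n",
              p$tp, p$fp, p$fn, p$precision, p$recall, p$f1, x$ap))
  m <- x$macro
  cat(sprintf("  macro:  P %.3f R %.3f F1 %.3f | MCE median %.2f px | count diff median %.1f%%\n",
              m$precision$mean, m$recall$mean, m$f1$mean,
              m$mce$median, m$count_diff_pct$median))
  invisible(x)
}
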