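test_that("IOU matches hand and grid-oracle values", {
  a <- bbox(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bbox(20, 20, 30, 30)), 0)
  expect_equal(iou(a, bbox(5, 0, 15, 10)), 1 / 3, tolerance = 1e-12)
  expect_error(iou(a, data.frame(x_min = 1, y_min = 1, x_max = 1, y_max = 5)),
               "degenerate")

  set.seed(12)
  for (k in 1:20) {
    b1 <- random_box(40)
    b2 <- random_box(40)
    expect_lt(abs(iou(b1, b2) - iou_grid_oracle(b1, b2)), 1e-3)
  }
})

test_that("greedy matching follows the one-ground-truth-one-match rule", {
  gt <- bbox(0, 0, 10, 10)
  det <- bbox(c(0, 1), c(0, 1), c(10, 11), c(10, 11), score = c(0.9, 0.8))
  m <- match_detections(det, gt)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$det, 1) # the higher-scoring one
  expect_equal(m$fp_indices, 2)
  expect_equal(length(m$fn_indices), 0)

  # disjoint sets: all FP / all FN
  m2 <- match_detections(bbox(0, 0, 5, 5, score = 0.7), bbox(50, 50, 60, 60))
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$fp_indices, 1)
  expect_equal(m2$fn_indices, 1)
})

test_that("greedy matching equals the enumeration oracle on small instances", {
  set.seed(23)
  for (k in 1:40) {
    n_det <- sample(0:4, 1)
    n_gt <- sample(0:4, 1)
    det <- random_boxes(n_det, lim = 25)
    gt <- random_boxes(n_gt, lim = 25)
    thr <- sample(c(0.3, 0.5), 1)
    m <- match_detections(det, gt, thr)
    assigned <- rep(NA_integer_, n_det)
    if (nrow(m$pairs) > 0) assigned[m$pairs$det] <- m$pairs$gt
    oracle <- match_oracle(det, gt, thr)
    expect_equal(assigned, oracle)
    # conservation
    expect_equal(nrow(m$pairs) + length(m$fp_indices), n_det)
    expect_equal(nrow(m$pairs) + length(m$fn_indices), n_gt)
    expect_true(all(m$pairs$iou >= thr))
  }
})

test_that("raising the IOU threshold never increases TP", {
  set.seed(31)
  det <- random_boxes(12, lim = 30)
  gt <- random_boxes(10, lim = 30)
  tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t) {
    nrow(match_detections(det, gt, t)$pairs)
  }, numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("precision/recall/F1 reproduce the published two-labeller totals", {
  # circuli detector vs ground truth across 87 transects
  m1 <- precision_recall_f1(5944, 617, 375)
  expect_equal(round(m1$recall, 2), 0.94)
  expect_equal(round(m1$f1, 2), 0.92)
  # second human labeller vs ground truth
  m2 <- precision_recall_f1(6060, 546, 259)
  expect_equal(round(m2$recall, 2), 0.96)
  expect_equal(round(m2$f1, 2), 0.94)

  # zero denominators are undefined markers, never silent 0 or 1
  z <- precision_recall_f1(0, 0, 5)
  expect_true(is.na(z$precision))
  expect_equal(z$recall, 0)
  expect_true(is.na(z$f1))
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("average precision has its closed-form and degenerate values", {
  # worked example: 102 correct, none false, 103 ground truths
  set.seed(5)
  ap <- average_precision(rep(TRUE, 102), 103)
  expect_equal(ap, 102 / 103, tolerance = 1e-12)
  expect_equal(round(100 * ap), 99)

  expect_equal(average_precision(rep(TRUE, 7), 7), 1.0)
  expect_equal(average_precision(FALSE, 4), 0.0)
  expect_error(average_precision(TRUE, 0), "at least 1")
})

test_that("average precision equals step-area integration on random rankings", {
  set.seed(17)
  for (k in 1:100) {
    n <- sample(1:40, 1)
    flags <- runif(n) < 0.6
    n_gt <- sum(flags) + sample(0:5, 1)
    if (n_gt == 0) n_gt <- 1
    expect_equal(average_precision(flags, n_gt), ap_step_oracle(flags, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to positive monotone score transforms", {
  set.seed(41)
  det <- random_boxes(15, lim = 30)
  gt <- random_boxes(8, lim = 30)
  rank_flags <- function(d) {
    m <- match_detections(d, gt, 0.3)
    flags <- seq_len(nrow(d)) %in% m$pairs$det
    flags[order(-d$score)]
  }
  f1 <- rank_flags(det)
  det2 <- det
  det2$score <- (det$score^3 + det$score) / 2 # strictly increasing map
  det2$score <- det2$score / max(det2$score)
  f2 <- rank_flags(det2)
  expect_equal(average_precision(f1, 8), average_precision(f2, 8))
})

test_that("mean centre error averages matched pairs only", {
  gt <- bbox(c(0, 20), c(0, 0), c(10, 30), c(10, 10))
  det <- bbox(c(2, 20), c(0, 2), c(12, 30), c(10, 12), score = c(0.9, 0.8))
  m <- match_detections(det, gt)
  expect_equal(mean_center_error(m, det, gt), 2) # offsets (2,0) and (0,2)

  same <- bbox(c(0, 20), c(0, 0), c(10, 30), c(10, 10), score = c(0.9, 0.8))
  expect_equal(mean_center_error(match_detections(same, gt), same, gt), 0)

  none <- match_detections(bbox(90, 90, 99, 99, score = 0.9), gt)
  expect_true(is.na(mean_center_error(none, bbox(90, 90, 99, 99, score = 0.9),
                                      gt)))

  # random matched set equals direct per-pair recomputation
  set.seed(13)
  d <- random_boxes(10, lim = 20)
  g <- random_boxes(10, lim = 20)
  mm <- match_detections(d, g, 0.2)
  if (nrow(mm$pairs) > 0) {
    direct <- mean(vapply(seq_len(nrow(mm$pairs)), function(i) {
      dc <- bbox_centers(d[mm$pairs$det[i], ])
      gc <- bbox_centers(g[mm$pairs$gt[i], ])
      sqrt(sum((dc - gc)^2))
    }, numeric(1)))
    expect_equal(mean_center_error(mm, d, g), direct, tolerance = 1e-12)
  }
})

test_that("count difference percentage is signed and guarded", {
  expect_equal(count_difference_pct(103, 100), 3)
  expect_equal(count_difference_pct(100, 100), 0)
  expect_equal(count_difference_pct(95, 100), -5)
  expect_error(count_difference_pct(10, 0), "at least 1")
})

test_that("dataset evaluation pools counts and preserves conservation", {
  set.seed(19)
  dets <- list()
  gts <- list()
  for (t in 1:6) {
    id <- paste0("tr", t)
    dets[[id]] <- random_boxes(sample(3:8, 1), lim = 50)
    gts[[id]] <- random_boxes(sample(3:8, 1), lim = 50)
  }
  ev <- evaluate_dataset(dets, gts, iou_threshold = 0.4)
  expect_equal(ev$pooled$tp + ev$pooled$fp,
               sum(vapply(dets, nrow, numeric(1))))
  expect_equal(ev$pooled$tp + ev$pooled$fn,
               sum(vapply(gts, nrow, numeric(1))))
  expect_equal(sum(vapply(ev$per_transect, `[[`, numeric(1), "tp")),
               ev$pooled$tp)

  # single transect pools to that transect's numbers
  one <- evaluate_dataset(dets[1], gts[1], iou_threshold = 0.4)
  expect_equal(one$pooled$tp, ev$per_transect[[1]]$tp)

  expect_error(evaluate_dataset(dets, gts[-1], 0.5), "tr1|align")
})

test_that("swapping detections and ground truths swaps the error structure", {
  # two labellers marking the same objects with independent jitter, plus a
  # few boxes unique to each labeller
  set.seed(29)
  grid <- expand.grid(x = seq(0, 90, by = 30), y = seq(0, 90, by = 30))
  jittered <- function(extra_at) {
    out <- bbox(grid$x + runif(16, -2, 2), grid$y + runif(16, -2, 2),
                grid$x + 20 + runif(16, -2, 2), grid$y + 20 + runif(16, -2, 2),
                score = runif(16))
    rbind(out, bbox(extra_at, 120, extra_at + 10, 130, score = runif(1)))
  }
  a <- jittered(0)
  b <- jittered(50)
  ev_ab <- evaluate_dataset(list(t = a), list(t = b), 0.4)
  ev_ba <- evaluate_dataset(list(t = b), list(t = a), 0.4)
  expect_equal(ev_ab$pooled$fp, ev_ba$pooled$fn)
  expect_equal(ev_ab$pooled$fn, ev_ba$pooled$fp)
  expect_equal(ev_ab$pooled$precision, ev_ba$pooled$recall)
  expect_equal(ev_ab$pooled$recall, ev_ba$pooled$precision)
})
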