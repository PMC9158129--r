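# A prediction/ground-truth pair with mask IoU exactly `iou` (subset mask).
subset_pair <- function(iou, n_gt_px = 10, h = 6, w = 12) {
  gt <- matrix(FALSE, h, w); gt[2, 2:(1 + n_gt_px)] <- TRUE
  pred <- matrix(FALSE, h, w); pred[2, 2:(1 + round(iou * n_gt_px))] <- TRUE
  list(pred = pred, gt = gt)
}

scored_det <- function(mask, score, id = 1L) {
  detection(mask_to_box(mask), mask, p_cls = score, p_box = 1, iou_mask = 1,
            score = score, instance_id = id)
}

test_that("greedy matching consumes each ground truth once", {
  f <- subset_pair(1)
  d <- scored_det(f$gt, 0.9)
  for (thr in seq(0.5, 0.95, by = 0.05)) {
    m <- match_detections(list(d), list(f$gt), thr)
    expect_true(m$tp)
  }

  # two detections on one ground truth: only the higher-scoring one matches
  d2 <- scored_det(f$gt, 0.6, id = 2L)
  m <- match_detections(list(d, d2), list(f$gt), 0.5)
  expect_identical(m$tp, c(TRUE, FALSE))
  expect_identical(m$index[1], 1L)

  # the inclusive comparator admits an exact-threshold match
  f7 <- subset_pair(0.7)
  m7 <- match_detections(list(scored_det(f7$pred, 0.9)), list(f7$gt), 0.7)
  expect_true(m7$tp)
})

test_that("matching agrees with independent greedy bookkeeping", {
  set.seed(161)
  for (rep in 1:30) {
    gts <- lapply(1:4, function(i) rand_blob(20, 20))
    dets <- lapply(1:6, function(i) {
      m <- rand_blob(20, 20)
      scored_det(m, runif(1), id = i)
    })
    thr <- runif(1, 0.1, 0.6)
    got <- match_detections(dets, gts, thr)

    # oracle: same contract, written independently
    sc <- vapply(dets, `[[`, numeric(1), "score")
    ord <- order(-sc, vapply(dets, `[[`, integer(1), "instance_id"))
    free <- rep(TRUE, length(gts))
    exp_tp <- logical(length(dets))
    for (i in ord) {
      ious <- vapply(seq_along(gts), function(j)
        if (free[j]) oracle_mask_iou(dets[[i]]$mask, gts[[j]]) else -1,
        numeric(1))
      if (max(ious) >= thr) { exp_tp[i] <- TRUE; free[which.max(ious)] <- FALSE }
    }
    expect_identical(got$tp, exp_tp[got$index])
  }
})

test_that("average precision reproduces hand-enumerated PR curves", {
  expect_identical(average_precision(c(TRUE, TRUE), c(0.9, 0.8), 2), 1)
  expect_identical(average_precision(logical(0), numeric(0), 3), 0)
  expect_identical(average_precision(TRUE, 0.9, 0), 0)

  # (TP, FP, TP) against 2 gts: PR points (0.5,1), (0.5,0.5), (1,2/3);
  # envelope 1 up to recall 0.5, then 2/3
  ap <- average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2)
  expect_equal(ap, (51 * 1 + 50 * (2 / 3)) / 101)
})

test_that("average precision agrees with the 101-point scan oracle", {
  set.seed(171)
  for (rep in 1:200) {
    n <- sample(1:12, 1)
    tp <- runif(n) < 0.5
    sc <- runif(n)
    n_gt <- sample(0:6, 1)
    tp[cumsum(tp) > n_gt] <- FALSE  # cannot have more TPs than gts
    expect_equal(average_precision(tp, sc, n_gt),
                 oracle_average_precision(tp, sc, n_gt), tolerance = 1e-12)
  }
})

test_that("AP^M over the threshold ladder behaves on canonical fixtures", {
  gts <- lapply(1:3, function(i) {
    m <- matrix(FALSE, 20, 20); m[(6 * i - 5):(6 * i - 2), 3:14] <- TRUE; m
  })
  perfect <- lapply(seq_along(gts), function(i) scored_det(gts[[i]], 0.9, i))
  r <- ap_m(perfect, gts)
  expect_identical(c(r$ap_m, r$ap50, r$ap75), c(1, 1, 1))
  expect_equal(r$ap_per_threshold, rep(1, 10))

  # one detection at IoU exactly 0.7: AP 1 for thresholds up to 0.70
  f <- subset_pair(0.7)
  expect_equal(mask_iou(f$pred, f$gt), 0.7)
  r7 <- ap_m(list(scored_det(f$pred, 0.9)), list(f$gt))
  expect_equal(c(r7$ap_m, r7$ap50, r7$ap75), c(0.5, 1, 0))

  r0 <- ap_m(list(), gts)
  expect_equal(c(r0$ap_m, r0$ap50, r0$ap75), c(0, 0, 0))
})

test_that("AP is monotone in threshold and responds correctly to TP/FP", {
  set.seed(181)
  for (rep in 1:10) {
    gts <- lapply(1:4, function(i) rand_blob(20, 20))
    dets <- lapply(1:5, function(i) scored_det(rand_blob(20, 20), runif(1), i))
    r <- ap_m(dets, gts)
    expect_true(all(diff(r$ap_per_threshold) <= 1e-12))
    expect_identical(r$ap50, r$ap_per_threshold[1])
    expect_identical(r$ap75, r$ap_per_threshold[6])
    expect_equal(r$ap_m, mean(r$ap_per_threshold), tolerance = 1e-12)

    # a lowest-scoring far-off FP never raises any AP
    fp_mask <- matrix(FALSE, 20, 20); fp_mask[20, 20] <- TRUE
    worse <- c(dets, list(scored_det(fp_mask, 1e-4, 99L)))
    r_fp <- ap_m(worse, gts)
    expect_true(all(r_fp$ap_per_threshold <= r$ap_per_threshold + 1e-12))

    # adding a perfect detection of an unmatched gt never lowers AP
    better <- c(dets, list(scored_det(gts[[1]], 0.999, 100L)))
    r_tp <- ap_m(better, gts)
    expect_true(all(r_tp$ap_per_threshold >= r$ap_per_threshold - 1e-12))
  }
})

test_that("multi-image pooling ranks detections jointly", {
  f1 <- subset_pair(1); f2 <- subset_pair(0.6)
  det_sets <- list(list(scored_det(f1$gt, 0.9)),
                   list(scored_det(f2$pred, 0.95, 2L)))
  gt_sets <- list(list(f1$gt), list(f2$gt))
  r <- ap_m(det_sets, gt_sets)
  expect_identical(r$n_gt, 2L)
  # at threshold 0.5 both are TPs; above 0.6 the higher-scoring image-2
  # detection turns FP and halves precision at full recall
  expect_identical(r$ap50, 1)
  expect_equal(r$ap_per_threshold[4],
               average_precision(c(FALSE, TRUE), c(0.95, 0.9), 2))
})
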