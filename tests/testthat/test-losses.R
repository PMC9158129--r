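# A fixture whose per-part IoUs on the 2x2 grid are exactly (0.5, 1, 1, 1):
# the prediction misses half the ground truth of the top-left cell.
quadrant_fixture <- function() {
  gt <- matrix(FALSE, 16, 16); gt[5:12, 5:12] <- TRUE  # 8x8 solid, 64 px
  pred <- gt
  pred[5:6, 5:8] <- FALSE  # remove 8 of the 16 px of the top-left cell
  part <- partition_grid(gt, 2, 2)
  list(gt = gt, pred = pred, part = part)
}

test_that("negative-log-IoU loss hits its closed-form values", {
  gt <- matrix(FALSE, 10, 10); gt[2:5, 2:9] <- TRUE
  expect_identical(iou_loss(gt, gt), 0)

  # half-overlapping congruent rectangles: IoU = 1/3 -> loss ln 3;
  # and a subset with IoU exactly 0.5 -> loss ln 2
  half <- gt; half[2:3, 2:9] <- FALSE
  expect_equal(mask_iou(half, gt), 0.5)
  expect_equal(iou_loss(half, gt), log(2))

  disj <- matrix(FALSE, 10, 10); disj[8:9, 1:4] <- TRUE
  expect_equal(iou_loss(disj, gt), -log(1e-7))
  expect_true(is.finite(iou_loss(disj, gt)))
  expect_error(iou_loss(gt, matrix(FALSE, 10, 10)), "empty")
})

test_that("K=1 partition reduces the K-IoU loss to the IoU loss exactly", {
  set.seed(61)
  for (i in 1:50) {
    gt <- rand_blob(); pred <- rand_mask(p = 0.4)
    part <- partition_grid(gt, 1, 1)
    expect_identical(k_iou_loss(pred, gt, part), iou_loss(pred, gt))
  }
})

test_that("K-IoU loss matches hand arithmetic on the quadrant fixture", {
  f <- quadrant_fixture()
  expect_equal(f$part$delta, rep(0.25, 4))
  expect_equal(per_part_iou(f$pred, f$gt, f$part), c(0.5, 1, 1, 1))
  expect_equal(k_iou_loss(f$pred, f$gt, f$part, weighted = TRUE),
               0.25 * log(2))
  expect_equal(k_iou_loss(f$pred, f$gt, f$part, weighted = FALSE), log(2))
  # the partitioned penalties bracket the diluted overall loss
  expect_gt(k_iou_loss(f$pred, f$gt, f$part, weighted = FALSE),
            iou_loss(f$pred, f$gt))
  expect_lte(k_iou_loss(f$pred, f$gt, f$part, weighted = TRUE),
             k_iou_loss(f$pred, f$gt, f$part, weighted = FALSE))
})

test_that("weighted K-IoU never exceeds the unweighted variant", {
  set.seed(71)
  for (i in 1:100) {
    gt <- rand_blob(); pred <- rand_mask(p = 0.4)
    part <- partition_grid(gt, sample(1:3, 1), sample(1:3, 1))
    expect_lte(k_iou_loss(pred, gt, part, weighted = TRUE),
               k_iou_loss(pred, gt, part, weighted = FALSE) + 1e-12)
  }
})

test_that("degrading one cell never decreases the K-IoU loss", {
  set.seed(81)
  for (i in 1:50) {
    gt <- rand_blob()
    part <- partition_grid(gt, 2, 2)
    pred <- gt
    active <- which(part$delta > 0)
    cell <- sample(active, 1)
    inside <- which(gt & part$cell == cell)
    if (length(inside) < 2) next
    l0 <- k_iou_loss(pred, gt, part)
    pred[inside[1]] <- FALSE
    l1 <- k_iou_loss(pred, gt, part)
    pred[inside[2]] <- FALSE
    l2 <- k_iou_loss(pred, gt, part)
    expect_gte(l1, l0 - 1e-12)
    expect_gte(l2, l1 - 1e-12)
  }
})

test_that("all losses stay finite for fully disjoint masks", {
  gt <- matrix(FALSE, 16, 16); gt[2:7, 2:7] <- TRUE
  pred <- matrix(FALSE, 16, 16); pred[10:15, 10:15] <- TRUE
  part <- partition_grid(gt, 4, 4)
  expect_true(is.finite(iou_loss(pred, gt)))
  expect_true(is.finite(k_iou_loss(pred, gt, part, weighted = TRUE)))
  expect_true(is.finite(k_iou_loss(pred, gt, part, weighted = FALSE)))
})

test_that("smooth-L1 loss follows its piecewise closed form", {
  expect_identical(smooth_l1(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(smooth_l1(c(0.5, 0, 0, 0)), 0.125 / 4)
  expect_equal(smooth_l1(c(2, 0, 0, 0)), 1.5 / 4)
  expect_equal(smooth_l1(c(-2, 0.5, 0, 0)), (1.5 + 0.125) / 4)
  expect_error(smooth_l1(c(Inf, 0, 0, 0)), "finite")
  expect_error(smooth_l1(c(1, 2, 3)), "length 4")
})

test_that("regression confidence is a bijection onto (0, 1]", {
  expect_identical(p_box(0), 1)
  expect_equal(p_box(0.5), 1 - tanh(0.5))
  grid <- 10^seq(-6, 2, length.out = 50)
  v <- p_box(grid)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) < 0))  # strictly decreasing
  expect_lt(p_box(50), 1e-12)   # saturates toward 0
  expect_gt(p_box(1e6), 0)      # but never reaches it
  expect_error(p_box(-0.1), "non-negative")
})

test_that("head supervision losses match their closed forms", {
  gt <- matrix(FALSE, 4, 4); gt[1:2, 1:2] <- TRUE
  h <- head_losses(p_cls_pred = 1, cls_target = 1,
                   pbox_pred = 1, pbox_target = 1,
                   mask_pred = gt, mask_target = gt,
                   iou_pred = 0.8, iou_true = 0.8)
  expect_lt(h$l_cls, 1e-6); expect_lt(h$l_pbox, 1e-6)
  expect_lt(h$l_mask, 1e-6); expect_identical(h$l_ioumask, 0)

  h2 <- head_losses(0.5, 1, 0.5, 1, gt, gt, 0.9, 0.7)
  expect_equal(h2$l_cls, log(2))
  expect_equal(h2$l_pbox, log(2), tolerance = 1e-6)
  expect_equal(h2$l_ioumask, 0.04)
  expect_error(head_losses(1.5, 1, 1, 1, gt, gt, 1, 1), "\\[0, 1\\]")
  expect_error(head_losses(1, 1, 1, 1, gt, matrix(FALSE, 2, 2), 1, 1),
               "dimensions differ")
})

test_that("the loss ledger sums its parts", {
  z <- aggregate_losses(0, 0, 0, 0, 0, 0)
  expect_identical(z$total, 0)
  l <- aggregate_losses(1, 1, 1, 1, 1, 1)
  expect_identical(c(l$l_box, l$l_seg, l$total), c(3, 3, 6))

  set.seed(91)
  for (i in 1:20) {
    v <- runif(6, 0, 5)
    l <- aggregate_losses(v[1], v[2], v[3], v[4], v[5], v[6])
    expect_equal(l$l_box, v[1] + v[2] + v[3], tolerance = 1e-12)
    expect_equal(l$l_seg, v[4] + v[5] + v[6], tolerance = 1e-12)
    expect_equal(l$total, sum(v), tolerance = 1e-12)
  }
  expect_error(aggregate_losses(-1, 0, 0, 0, 0, 0), "non-negative")
})
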