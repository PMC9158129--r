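test_that("mask IoU matches pixel counting and its conventions", {
  a <- matrix(FALSE, 8, 8); a[2:4, 2:5] <- TRUE   # 3x4 rectangle, 12 px
  b <- matrix(FALSE, 8, 8); b[2:4, 4:7] <- TRUE   # shifted copy
  expect_equal(sum(a & b), 6)
  expect_equal(mask_iou(a, b), 6 / 18)

  expect_identical(mask_iou(a, a), 1)
  disj <- matrix(FALSE, 8, 8); disj[7:8, 1:2] <- TRUE
  expect_identical(mask_iou(a, disj), 0)
  empty <- matrix(FALSE, 8, 8)
  expect_identical(mask_iou(empty, empty), 0)
  expect_error(mask_iou(a, matrix(FALSE, 4, 4)), "dimensions differ")
})

test_that("mask IoU is symmetric, bounded, and exact on random pairs", {
  set.seed(11)
  for (i in 1:50) {
    a <- rand_mask(); b <- rand_mask()
    v <- mask_iou(a, b)
    expect_identical(v, mask_iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, oracle_mask_iou(a, b))
  }
})

test_that("soft masks reduce to hard IoU on 0/1 input and stay bounded", {
  set.seed(12)
  a <- rand_mask(); b <- rand_mask()
  expect_equal(mask_iou(a * 1, b * 1), mask_iou(a, b))
  p <- matrix(runif(64), 8, 8); g <- matrix(runif(64) > 0.5, 8, 8)
  v <- mask_iou(p, g * 1)
  expect_gte(v, 0); expect_lte(v, 1)
  expect_error(mask_iou(p * 2, g * 1), "\\[0, 1\\]")
})

test_that("box IoU follows the half-open convention", {
  expect_identical(box_iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1)
  expect_equal(box_iou(box(0, 0, 10, 10), box(5, 0, 15, 10)), 1 / 3)
  expect_identical(box_iou(box(0, 0, 2, 2), box(10, 10, 12, 12)), 0)
  # boxes sharing only an edge do not intersect
  expect_identical(box_iou(box(0, 0, 5, 5), box(5, 0, 10, 5)), 0)
  expect_error(box(0, 0, 0, 5), "degenerate")
})

test_that("mask_to_box is the tight half-open box", {
  m <- matrix(FALSE, 5, 6); m[3, 4] <- TRUE  # pixel (r=2, c=3) 0-based
  expect_equal(unclass(mask_to_box(m)), c(x1 = 3, y1 = 2, x2 = 4, y2 = 3))

  full <- matrix(TRUE, 7, 9)
  expect_equal(unclass(mask_to_box(full)), c(x1 = 0, y1 = 0, x2 = 9, y2 = 7))

  expect_error(mask_to_box(matrix(FALSE, 3, 3)), "empty mask")

  set.seed(21)
  for (i in 1:25) {
    m <- rand_blob()
    expect_equal(unclass(mask_to_box(m)), oracle_mask_box(m))
  }
})

test_that("partition weights are the ground-truth shares", {
  solid <- matrix(FALSE, 12, 12); solid[3:10, 3:10] <- TRUE
  p <- partition_grid(solid, 2, 2)
  expect_equal(p$delta, rep(0.25, 4))

  # 40-pixel mask with 30 pixels in the top half of its bounding box
  g <- matrix(FALSE, 10, 10)
  g[1:4, 1:7] <- TRUE               # 28
  g[1, 8:9] <- TRUE                 # 30 in rows 1-4
  g[5:8, 1:2] <- TRUE               # 8
  g[5:6, 3] <- TRUE                 # 10 in rows 5-8
  expect_equal(sum(g), 40)
  p21 <- partition_grid(g, 2, 1)
  expect_equal(p21$delta, c(0.75, 0.25))

  p1 <- partition_grid(g, 1, 1)
  expect_equal(p1$delta, 1)
  expect_true(all(p1$cell == 1L))

  expect_error(partition_grid(matrix(FALSE, 4, 4), 2, 2), "empty")
  expect_error(partition_grid(g, 0, 2), ">= 1")
})

test_that("partition cells tile the image and absorb outside pixels", {
  set.seed(31)
  for (i in 1:20) {
    g <- rand_blob()
    for (k in c(1, 2, 3)) {
      p <- partition_grid(g, k, k)
      expect_true(all(p$cell >= 1 & p$cell <= p$k))
      expect_equal(sum(p$delta), 1, tolerance = 1e-12)
      counts <- tabulate(p$cell[g], nbins = p$k)
      expect_identical(p$delta == 0, counts == 0)
    }
  }
})

test_that("uneven splits put larger cells first", {
  g <- matrix(FALSE, 3, 7); g[2, 2:6] <- TRUE  # 1x5 bbox, cols 2..6
  p <- partition_grid(g, 1, 2)
  # 5 columns split 3 + 2, larger cell on the left
  expect_equal(sum(p$cell[2, 2:6] == 1L), 3)
  expect_equal(sum(p$cell[2, 2:6] == 2L), 2)
  # boundary cells absorb everything outside the bbox
  expect_true(all(p$cell[, 1] == p$cell[2, 2]))
  expect_true(all(p$cell[, 7] == p$cell[2, 6]))
})

test_that("per-part IoU agrees with a per-cell pixel oracle", {
  set.seed(41)
  for (i in 1:40) {
    gt <- rand_blob(); pred <- rand_mask(p = 0.4)
    part <- partition_grid(gt, sample(1:3, 1), sample(1:3, 1))
    expect_equal(per_part_iou(pred, gt, part),
                 oracle_per_part_iou(pred, gt, part))
  }
})

test_that("per-part IoU identity and empty-cell conventions hold", {
  gt <- matrix(FALSE, 10, 10); gt[2:9, 2:9] <- TRUE
  part <- partition_grid(gt, 2, 2)
  ious <- per_part_iou(gt, gt, part)
  expect_equal(ious[part$delta > 0], rep(1, sum(part$delta > 0)))
  empty <- matrix(FALSE, 10, 10)
  expect_equal(per_part_iou(empty, gt, part), rep(0, 4))
})

test_that("overall IoU lies between the extreme per-cell IoUs", {
  set.seed(51)
  checked <- 0
  for (i in 1:200) {
    gt <- rand_blob(); pred <- rand_mask(p = 0.4)
    part <- partition_grid(gt, 2, 2)
    ious <- per_part_iou(pred, gt, part)
    uni <- vapply(seq_len(part$k), function(j)
      sum((pred | gt)[part$cell == j]), numeric(1))
    if (any(uni == 0)) next  # mediant bound needs all cells non-trivial
    checked <- checked + 1
    overall <- mask_iou(pred, gt)
    expect_gte(overall, min(ious) - 1e-12)
    expect_lte(overall, max(ious) + 1e-12)
  }
  expect_gt(checked, 50)
})
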