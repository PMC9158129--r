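# Independent brute-force oracles. These deliberately take the slow,
# obvious route (explicit scans and loops) so they share no code path with
# the package implementations they check.

rand_mask <- function(h = 32, w = 32, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# A random connected-ish blob: a filled rectangle plus random speckle.
rand_blob <- function(h = 32, w = 32) {
  m <- matrix(FALSE, h, w)
  r <- sort(sample.int(h, 2)); c <- sort(sample.int(w, 2))
  m[r[1]:r[2], c[1]:c[2]] <- TRUE
  m[matrix(c(sample.int(h, 5, TRUE), sample.int(w, 5, TRUE)), ncol = 2)] <- TRUE
  m
}

# Pixel-scan IoU: explicit elementwise counting.
oracle_mask_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(a)) {
    if (a[[i]] && b[[i]]) inter <- inter + 1L
    if (a[[i]] || b[[i]]) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

# Exhaustive min/max scan for the tight bounding box.
oracle_mask_box <- function(m) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (m[r, c]) {
      rmin <- min(rmin, r); rmax <- max(rmax, r)
      cmin <- min(cmin, c); cmax <- max(cmax, c)
    }
  }
  c(x1 = cmin - 1, y1 = rmin - 1, x2 = cmax, y2 = rmax)
}

# Per-cell IoU by restricting both masks to each cell region.
oracle_per_part_iou <- function(pred, gt, part) {
  vapply(seq_len(part$k), function(i) {
    sel <- part$cell == i
    p <- pred & sel; g <- gt & sel
    inter <- sum(p & g); uni <- sum(p | g)
    if (uni == 0) 0 else inter / uni
  }, numeric(1))
}

# Greedy NMS by repeated explicit argmax over the survivors.
oracle_greedy_nms <- function(iou_mat, scores, ids, threshold) {
  remaining <- seq_along(scores)
  kept <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (i in remaining) {
      if (scores[i] > scores[best] ||
          (scores[i] == scores[best] && ids[i] < ids[best])) best <- i
    }
    kept <- c(kept, best)
    keepers <- integer(0)
    for (i in remaining) {
      if (i != best && !(iou_mat[best, i] > threshold))
        keepers <- c(keepers, i)
    }
    remaining <- keepers
  }
  kept
}

# 101-point AP by direct scan: for each recall level take the best
# precision among PR points at or beyond it.
oracle_average_precision <- function(tp, scores, n_gt) {
  if (n_gt == 0 || length(tp) == 0) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  recall <- ctp / n_gt
  precision <- ctp / seq_along(tp)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (i in seq_along(recall)) {
      if (recall[i] >= r && precision[i] > best) best <- precision[i]
    }
    total <- total + best
  }
  total / 101
}

# Random scored detections on a shared small grid (for NMS/AP checks).
rand_detections <- function(n, h = 24, w = 24, tie_prob = 0) {
  scores <- runif(n)
  if (tie_prob > 0) {
    dup <- runif(n) < tie_prob
    scores[dup] <- sample(scores, sum(dup), replace = TRUE)
  }
  lapply(seq_len(n), function(i) {
    r <- sort(sample.int(h, 2)); c <- sort(sample.int(w, 2))
    m <- matrix(FALSE, h, w)
    m[r[1]:r[2], c[1]:c[2]] <- TRUE
    detection(box(c[1] - 1 + runif(1, -0.3, 0.3), r[1] - 1,
                  c[2] + runif(1, 0, 2), r[2] + runif(1, 0, 2)),
              m, p_cls = scores[i], p_box = runif(1), iou_mask = runif(1),
              score = scores[i], instance_id = i)
  })
}

pairwise_iou_from <- function(dets, fun) {
  n <- length(dets)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- fun(dets[[i]], dets[[j]])
  m
}
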