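# COCO-style mask average precision for a single category. Conventions
# follow the COCO evaluator: greedy score-ordered matching with each ground
# truth used at most once, inclusive (>=) IoU comparison at matching, and
# 101-point interpolation of the precision-recall curve. No maxDets cap is
# applied: scene instance counts here are small.

.ap_thresholds <- seq(0.5, 0.95, by = 0.05)

#' Greedy matching of detections against ground-truth masks
#'
#' Detections are visited in descending score order (ties broken by lower
#' instance id). Each detection is matched to the unmatched ground truth
#' with which it has the highest mask IoU; it is a true positive iff that
#' IoU is at least the threshold, and that ground truth is then consumed.
#' Everything else is a false positive.
#'
#' @param dets list of scored detections on one grid.
#' @param gts list of non-empty ground-truth masks on that grid.
#' @param iou_threshold mask-IoU threshold in \[0, 1\].
#' @param score_key order by \code{"corrected"} score or \code{"raw"} p_cls.
#' @return data.frame with one row per detection in traversal order:
#'   \code{index} (into \code{dets}), \code{score}, \code{tp} (logical),
#'   \code{matched_gt} (index into \code{gts} or NA), \code{iou}.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5,
                             score_key = c("corrected", "raw")) {
  .assert_detections(dets)
  score_key <- match.arg(score_key)
  if (length(gts) > 0 && length(dets) > 0)
    .assert_same_dim(dets[[1]]$mask, gts[[1]])
  n <- length(dets)
  scores <- if (n) .det_scores(dets, score_key) else numeric(0)
  ids <- vapply(dets, function(d) d$instance_id, integer(1))
  ord <- order(-scores, ids)

  iou_mat <- matrix(0, n, length(gts))
  for (i in seq_len(n)) for (j in seq_along(gts))
    iou_mat[i, j] <- mask_iou(dets[[i]]$mask, gts[[j]])

  gt_free <- rep(TRUE, length(gts))
  tp <- logical(n); matched <- rep(NA_integer_, n); best_iou <- numeric(n)
  for (i in ord) {
    if (any(gt_free)) {
      cand <- which(gt_free)
      j <- cand[which.max(iou_mat[i, cand])]
      best_iou[i] <- iou_mat[i, j]
      if (iou_mat[i, j] >= iou_threshold) {
        tp[i] <- TRUE; matched[i] <- j; gt_free[j] <- FALSE
      }
    }
  }
  data.frame(index = ord, score = scores[ord], tp = tp[ord],
             matched_gt = matched[ord], iou = best_iou[ord])
}

#' 101-point interpolated average precision
#'
#' Standard COCO AP: detections sorted by descending score, the precision
#' envelope (running maximum from the right) is sampled at the 101 recall
#' points \code{0, 0.01, ..., 1} and averaged. With no ground truth the AP
#' is defined as 0.
#'
#' @param tp logical vector of per-detection true-positive labels.
#' @param scores matching score vector (used to sort; may already be
#'   sorted descending).
#' @param n_gt number of ground-truth instances (>= 0).
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(tp, scores, n_gt) {
  if (length(tp) != length(scores))
    stop("tp and scores must have equal length", call. = FALSE)
  if (n_gt < 0) stop("n_gt must be >= 0", call. = FALSE)
  if (n_gt == 0 || length(tp) == 0) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  recall <- ctp / n_gt
  precision <- ctp / seq_along(tp)
  envelope <- rev(cummax(rev(precision)))
  rpts <- seq(0, 1, by = 0.01)
  # first PR point reaching each recall level; 0 beyond the achieved recall
  idx <- findInterval(rpts, recall, left.open = TRUE) + 1L
  p_at <- ifelse(idx <= length(envelope), envelope[pmin(idx, length(envelope))], 0)
  mean(p_at)
}

.pr_curve <- function(tp, scores, n_gt) {
  if (length(tp) == 0 || n_gt == 0)
    return(data.frame(recall = numeric(0), precision = numeric(0)))
  ord <- order(-scores)
  ctp <- cumsum(tp[ord])
  data.frame(recall = ctp / n_gt, precision = ctp / seq_along(ctp))
}

#' Mask average precision over the COCO threshold ladder
#'
#' AP is computed at each mask-IoU threshold 0.50, 0.55, ..., 0.95;
#' \code{ap_m} is their mean, \code{ap50} and \code{ap75} the values at
#' thresholds 0.50 and 0.75. Multiple images are pooled the COCO way:
#' matching is per image, then all detections are ranked jointly against
#' the total ground-truth count.
#'
#' @param dets detections of one image (list of [detection()]) or, for a
#'   multi-image evaluation, a list of such lists.
#' @param gts ground-truth masks of one image (list of matrices) or a list
#'   of such lists, parallel to \code{dets}.
#' @param score_key ranking score, \code{"corrected"} or \code{"raw"}.
#' @return Object of class \code{"eval_result"}: list with
#'   \code{ap_per_threshold} (length 10), \code{ap_m}, \code{ap50},
#'   \code{ap75}, \code{thresholds}, \code{n_gt} and \code{pr_curves}.
#' @export
ap_m <- function(dets, gts, score_key = c("corrected", "raw")) {
  score_key <- match.arg(score_key)
  single <- length(dets) == 0 || is_detection(dets[[1]])
  det_sets <- if (single) list(dets) else dets
  gt_sets <- if (single) list(gts) else gts
  if (length(det_sets) != length(gt_sets))
    stop("dets and gts must cover the same images", call. = FALSE)

  n_gt <- sum(lengths(gt_sets))
  aps <- numeric(length(.ap_thresholds))
  curves <- vector("list", length(.ap_thresholds))
  for (t in seq_along(.ap_thresholds)) {
    thr <- .ap_thresholds[t]
    tp <- logical(0); sc <- numeric(0)
    for (img in seq_along(det_sets)) {
      if (length(det_sets[[img]]) == 0) next
      m <- match_detections(det_sets[[img]], gt_sets[[img]], thr, score_key)
      tp <- c(tp, m$tp); sc <- c(sc, m$score)
    }
    aps[t] <- average_precision(tp, sc, n_gt)
    curves[[t]] <- .pr_curve(tp, sc, n_gt)
  }
  names(curves) <- sprintf("iou_%.2f", .ap_thresholds)
  structure(list(ap_per_threshold = aps, ap_m = mean(aps),
                 ap50 = aps[1], ap75 = aps[6],
                 thresholds = .ap_thresholds, n_gt = n_gt,
                 pr_curves = curves),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<mask AP over %d ground-truth instances>\n", x$n_gt))
  cat(sprintf("  AP^M  = %.4f   AP50 = %.4f   AP75 = %.4f\n",
              x$ap_m, x$ap50, x$ap75))
  cat("  per threshold:",
      paste(sprintf("%.2f:%.3f", x$thresholds, x$ap_per_threshold),
            collapse = " "), "\n")
  invisible(x)
}
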