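# Loss functions for the box and segmentation heads. All log-based losses
# clamp their argument at `eps` (default 1e-7) so that fully disjoint masks
# give a large but finite loss: a zero per-cell IoU would otherwise send the
# loss to infinity and, in a training setting, kill the gradient entirely.

.default_eps <- 1e-7

.clamp01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

.assert_nonempty_gt <- function(gt) {
  hard <- if (is.logical(gt)) gt else gt > 0
  if (!any(hard)) stop("ground-truth mask is empty", call. = FALSE)
}

#' Negative-log-IoU segmentation loss
#'
#' \eqn{L_{IoU} = -\ln(\max(IoU, \epsilon))} between a predicted mask and
#' its ground truth. Zero exactly when the masks agree (IoU 1); finite even
#' for disjoint masks thanks to the clamp.
#'
#' @param pred predicted mask (binary or soft, see [mask_iou()]).
#' @param gt non-empty ground-truth mask on the same grid.
#' @param eps clamp inside the log, default \code{1e-7}.
#' @return Non-negative scalar.
#' @export
iou_loss <- function(pred, gt, eps = .default_eps) {
  .assert_nonempty_gt(gt)
  -log(max(mask_iou(pred, gt), eps))
}

#' Partitioned K-IoU segmentation loss
#'
#' The ground truth is split into K grid cells (see [partition_grid()]) and
#' the loss is \eqn{-\sum_i w_i \ln(\max(IoU_i, \epsilon))} over cells that
#' contain ground truth. With \code{weighted = TRUE} (default) the weights
#' are the ground-truth shares \eqn{w_i = \delta_i}, so a segmentation
#' error is penalised in proportion to how much of the chromosome lives in
#' the affected cell; with \code{weighted = FALSE} every ground-truth-
#' bearing cell counts fully (\eqn{w_i = 1}), the harsher variant. Cells
#' with \eqn{\delta_i = 0} contribute nothing either way.
#'
#' A 1x1 partition reduces the loss exactly to [iou_loss()]. Because a
#' localized error cannot be diluted by well-segmented remote cells, the
#' unweighted loss is always at least the plain IoU loss when the error is
#' confined to one cell, and the weighted loss never exceeds the unweighted
#' one.
#'
#' @param pred predicted mask.
#' @param gt non-empty ground-truth mask on the same grid.
#' @param part partition from [partition_grid()]; defaults to the 2x2 grid
#'   of \code{gt}.
#' @param weighted use the delta weights (default) or unit weights.
#' @param eps clamp inside each log.
#' @return Non-negative scalar.
#' @export
k_iou_loss <- function(pred, gt, part = NULL, weighted = TRUE,
                       eps = .default_eps) {
  .assert_nonempty_gt(gt)
  if (is.null(part)) part <- partition_grid(gt, 2L, 2L)
  ious <- per_part_iou(pred, gt, part)
  active <- part$delta > 0
  w <- if (weighted) part$delta else as.numeric(active)
  -sum(w[active] * log(pmax(ious[active], eps)))
}

#' Smooth-L1 box-regression loss
#'
#' Mean over the four offset coordinates of the Huber-style penalty
#' \eqn{s(d) = 0.5 d^2} for \eqn{|d| < 1}, else \eqn{|d| - 0.5}, with
#' \eqn{d} the predicted-minus-target offset. Averaging (rather than
#' summing) keeps the loss scale comparable across box parameterizations.
#'
#' @param predicted,target numeric length-4 offset vectors (any common box
#'   offset parameterization; unitless).
#' @return Non-negative scalar.
#' @export
smooth_l1 <- function(predicted, target = numeric(4)) {
  if (length(predicted) != 4 || length(target) != 4)
    stop("offsets must have length 4", call. = FALSE)
  if (!all(is.finite(predicted)) || !all(is.finite(target)))
    stop("offsets must be finite", call. = FALSE)
  d <- abs(predicted - target)
  mean(ifelse(d < 1, 0.5 * d^2, d - 0.5))
}

#' Regression confidence from the regression loss
#'
#' \eqn{P_{Box} = 1 - \tanh(L_{Reg})}: a bijection from \eqn{[0, \infty)}
#' onto \eqn{(0, 1]} that equals 1 exactly for a perfect regression and
#' decays to 0 as the regression loss grows. Used as a localization-quality
#' proxy when correcting the classification confidence.
#'
#' Computed in the algebraically identical form \eqn{2 / (1 + e^{2 L})},
#' which keeps the tail positive long after \code{1 - tanh(l_reg)} would
#' round to exactly 0, and floored at the smallest positive double so the
#' codomain contract holds for any finite input.
#'
#' @param l_reg non-negative regression loss (vectorized).
#' @return Values in \code{(0, 1]}.
#' @export
p_box <- function(l_reg) {
  if (!is.numeric(l_reg) || anyNA(l_reg) || any(l_reg < 0))
    stop("l_reg must be non-negative", call. = FALSE)
  pmax(2 * stats::plogis(-2 * l_reg), .Machine$double.xmin)
}

.bce <- function(p, t, eps) {
  p <- .clamp01(p, eps)
  -(t * log(p) + (1 - t) * log(1 - p))
}

#' Supervision losses of the four auxiliary heads
#'
#' Binary cross-entropy for the classification head and for the regression-
#' confidence head (whose target is the [p_box()] transform of the realized
#' regression loss), mean per-pixel binary cross-entropy for the mask head,
#' and squared error to the true mask IoU for the mask-IoU head.
#'
#' @param p_cls_pred predicted foreground probability.
#' @param cls_target 0/1 class label.
#' @param pbox_pred,pbox_target predicted and target regression confidence,
#'   both in \[0, 1\].
#' @param mask_pred probability mask (matrix in \[0, 1\]).
#' @param mask_target binary ground-truth mask, same dimensions.
#' @param iou_pred,iou_true predicted and realized mask IoU in \[0, 1\].
#' @param eps probability clamp before logs.
#' @return Named list \code{l_cls}, \code{l_pbox}, \code{l_mask},
#'   \code{l_ioumask}.
#' @export
head_losses <- function(p_cls_pred, cls_target, pbox_pred, pbox_target,
                        mask_pred, mask_target, iou_pred, iou_true,
                        eps = .default_eps) {
  probs <- c(p_cls_pred, pbox_pred, pbox_target, iou_pred, iou_true)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!cls_target %in% c(0, 1))
    stop("cls_target must be 0 or 1", call. = FALSE)
  .assert_mask(mask_pred, "mask_pred"); .assert_mask(mask_target, "mask_target")
  .assert_same_dim(mask_pred, mask_target)
  list(
    l_cls = .bce(p_cls_pred, cls_target, eps),
    l_pbox = .bce(pbox_pred, pbox_target, eps),
    l_mask = mean(.bce(mask_pred * 1, mask_target * 1, eps)),
    l_ioumask = (iou_pred - iou_true)^2
  )
}

#' Assemble the per-proposal loss ledger
#'
#' The total training loss of one proposal is the sum of a box-head part
#' and a segmentation-head part:
#' \deqn{L = L_{Box} + L_{Seg}, \quad
#'       L_{Box} = L_{Cls} + L_{Reg} + L_{PBox}, \quad
#'       L_{Seg} = L_{Mask} + L_{K\mbox{-}IoU} + L_{IoUMask}.}
#'
#' @param l_cls,l_reg,l_pbox,l_mask,l_kiou,l_ioumask non-negative component
#'   losses.
#' @return Object of class \code{"loss_components"}: named list with the
#'   six components plus \code{l_box}, \code{l_seg} and \code{total}.
#' @export
aggregate_losses <- function(l_cls, l_reg, l_pbox, l_mask, l_kiou, l_ioumask) {
  comp <- c(l_cls = l_cls, l_reg = l_reg, l_pbox = l_pbox,
            l_mask = l_mask, l_kiou = l_kiou, l_ioumask = l_ioumask)
  if (anyNA(comp) || any(!is.finite(comp)) || any(comp < 0))
    stop("loss components must be finite and non-negative", call. = FALSE)
  out <- as.list(comp)
  out$l_box <- l_cls + l_reg + l_pbox
  out$l_seg <- l_mask + l_kiou + l_ioumask
  out$total <- out$l_box + out$l_seg
  structure(out, class = "loss_components")
}

#' @export
print.loss_components <- function(x, ...) {
  cat("<loss components>\n")
  cat(sprintf("  box head: cls %.4g + reg %.4g + pbox %.4g = %.4g\n",
              x$l_cls, x$l_reg, x$l_pbox, x$l_box))
  cat(sprintf("  seg head: mask %.4g + k-iou %.4g + ioumask %.4g = %.4g\n",
              x$l_mask, x$l_kiou, x$l_ioumask, x$l_seg))
  cat(sprintf("  total: %.4g\n", x$total))
  invisible(x)
}

#' @export
as.data.frame.loss_components <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
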