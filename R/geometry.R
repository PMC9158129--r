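# Pixel conventions used throughout the package:
#  - a binary mask is a logical (or 0/1, or [0,1]-probability) matrix,
#    rows = y, cols = x; an all-FALSE mask is legal ("empty mask");
#  - boxes are 0-based half-open [x1, x2) x [y1, y2) in pixel units, so the
#    single pixel at matrix cell (row r1, col c1) (1-based) has box
#    (c1-1, r1-1, c1, r1);
#  - empty-vs-empty IoU is defined as 0, never NaN.

.assert_mask <- function(m, name = "mask") {
  if (!is.matrix(m)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  if (is.logical(m)) return(invisible(m))
  if (!is.numeric(m)) stop(sprintf("`%s` must be logical or numeric", name), call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(m > 1))
    stop(sprintf("`%s` must have values in [0, 1]", name), call. = FALSE)
  invisible(m)
}

.assert_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
}

.mask_area <- function(m) sum(as.numeric(m))

#' Intersection-over-union of two masks
#'
#' Computes \eqn{|A \cap B| / |A \cup B|} for two pixel masks on the same
#' grid. Logical masks use exact pixel counting; numeric masks with values in
#' \[0, 1\] are treated as soft (probability) masks with intersection
#' \eqn{\sum p g} and union \eqn{\sum (p + g - p g)}, which coincides with
#' the hard definition on 0/1 input. Two empty masks have IoU 0 by
#' convention (such cells never carry weight in the partitioned loss, and 0
#' avoids spurious perfect scores in reports).
#'
#' @param a,b masks of identical dimensions (logical or numeric in \[0,1\]).
#' @return A single number in \[0, 1\].
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:5] <- TRUE
#' mask_iou(m, m)           # 1
#' mask_iou(m, !m & FALSE)  # 0: empty second mask
#' @export
mask_iou <- function(a, b) {
  .assert_mask(a, "a"); .assert_mask(b, "b")
  .assert_same_dim(a, b)
  if (is.logical(a) && is.logical(b)) {
    inter <- sum(a & b)
    uni <- sum(a | b)
  } else {
    a <- a * 1; b <- b * 1
    inter <- sum(a * b)
    uni <- sum(a + b - a * b)
  }
  if (uni == 0) 0 else inter / uni
}

#' Construct a bounding box
#'
#' Boxes are 0-based and half-open: \code{[x1, x2) x [y1, y2)} in pixels.
#' Degenerate (zero-area) boxes are rejected.
#'
#' @param x1,y1,x2,y2 box edges in pixels, \code{x2 > x1}, \code{y2 > y1}.
#' @return An object of class \code{"seg_box"} (named numeric length 4).
#' @export
box <- function(x1, y1, x2, y2) {
  v <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (anyNA(v) || any(!is.finite(v)))
    stop("box coordinates must be finite", call. = FALSE)
  if (v[["x2"]] <= v[["x1"]] || v[["y2"]] <= v[["y1"]])
    stop("degenerate box: need x2 > x1 and y2 > y1", call. = FALSE)
  structure(v, class = "seg_box")
}

.as_box <- function(b) {
  if (inherits(b, "seg_box")) return(b)
  if (is.numeric(b) && length(b) == 4) return(box(b[[1]], b[[2]], b[[3]], b[[4]]))
  stop("not a box: supply box() or a numeric (x1, y1, x2, y2)", call. = FALSE)
}

#' @export
print.seg_box <- function(x, ...) {
  cat(sprintf("<box [%g, %g) x [%g, %g), area %g px>\n",
              x[["x1"]], x[["x2"]], x[["y1"]], x[["y2"]], box_area(x)))
  invisible(x)
}

#' Box area in pixels
#' @param b a box.
#' @export
box_area <- function(b) {
  b <- .as_box(b)
  (b[["x2"]] - b[["x1"]]) * (b[["y2"]] - b[["y1"]])
}

#' Intersection-over-union of two boxes
#'
#' Half-open convention: boxes sharing only an edge have intersection 0.
#'
#' @param a,b boxes (see [box()]).
#' @return A single number in \[0, 1\].
#' @examples
#' box_iou(box(0, 0, 10, 10), box(5, 0, 15, 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- .as_box(a); b <- .as_box(b)
  iw <- min(a[["x2"]], b[["x2"]]) - max(a[["x1"]], b[["x1"]])
  ih <- min(a[["y2"]], b[["y2"]]) - max(a[["y1"]], b[["y1"]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' Tight bounding box of a mask
#'
#' @param m a non-empty binary mask.
#' @return The tight half-open box around the TRUE pixels.
#' @examples
#' m <- matrix(FALSE, 5, 6); m[3, 4] <- TRUE  # pixel (r=2, c=3) 0-based
#' mask_to_box(m)                             # [3,4) x [2,3)
#' @export
mask_to_box <- function(m) {
  .assert_mask(m)
  hard <- if (is.logical(m)) m else m > 0
  if (!any(hard)) stop("empty mask has no bounding box", call. = FALSE)
  rs <- range(row(hard)[hard])
  cs <- range(col(hard)[hard])
  box(cs[1] - 1, rs[1] - 1, cs[2], rs[2])
}

# Split `n` pixels into `k` integer runs differing by at most 1,
# larger runs first (top/left).
.even_split <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}

#' Partition a ground-truth mask into a K-cell grid
#'
#' Divides the tight bounding box of a ground-truth mask into
#' \code{rows x cols} cells of (as nearly as possible) equal size and
#' extends the boundary cells outward so that every pixel of the image
#' falls in exactly one cell; pixels outside the ground-truth box are
#' absorbed by the nearest boundary cell, so false-positive prediction
#' pixels anywhere on the grid are accounted for. Each cell \eqn{i}
#' carries the weight \eqn{\delta_i}, the share of the ground-truth pixels
#' that lie in it, so \eqn{\sum_i \delta_i = 1} and \eqn{\delta_i = 0}
#' exactly on cells without ground truth. Cell indices run row-major:
#' cell \eqn{(r, c)} is \eqn{(r-1) \cdot cols + c}.
#'
#' When integer cell sizes cannot be equal, the larger cells come first
#' (top rows, left columns); the split is deterministic.
#'
#' @param gt a non-empty binary ground-truth mask.
#' @param rows,cols grid shape, both >= 1; \code{K = rows * cols}.
#' @return An object of class \code{"partition_spec"}: list with
#'   \code{rows}, \code{cols}, \code{k}, \code{cell} (integer matrix, same
#'   dimensions as \code{gt}, values in \code{1..K}) and \code{delta}
#'   (numeric length K).
#' @seealso [per_part_iou()], [k_iou_loss()]
#' @export
partition_grid <- function(gt, rows = 2L, cols = 2L) {
  .assert_mask(gt, "gt")
  hard <- if (is.logical(gt)) gt else gt > 0
  if (!any(hard)) stop("cannot partition an empty ground-truth mask", call. = FALSE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("rows and cols must be integers >= 1", call. = FALSE)

  h <- nrow(gt); w <- ncol(gt)
  rr <- range(row(hard)[hard])
  cc <- range(col(hard)[hard])
  bh <- rr[2] - rr[1] + 1L
  bw <- cc[2] - cc[1] + 1L

  row_cell <- c(rep(1L, rr[1] - 1L),
                rep(seq_len(rows), times = .even_split(bh, rows)),
                rep(rows, h - rr[2]))
  col_cell <- c(rep(1L, cc[1] - 1L),
                rep(seq_len(cols), times = .even_split(bw, cols)),
                rep(cols, w - cc[2]))
  cell <- matrix(0L, h, w)
  cell[] <- (row_cell[row(cell)] - 1L) * cols + col_cell[col(cell)]

  k <- rows * cols
  counts <- tabulate(cell[hard], nbins = k)
  delta <- counts / sum(counts)

  structure(list(rows = rows, cols = cols, k = k, cell = cell, delta = delta),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("<partition %dx%d (K = %d)>\n", x$rows, x$cols, x$k))
  cat("delta:", paste(signif(x$delta, 4), collapse = " "), "\n")
  invisible(x)
}

.assert_partition <- function(part, grid_like) {
  if (!inherits(part, "partition_spec"))
    stop("`part` must come from partition_grid()", call. = FALSE)
  if (!identical(dim(part$cell), dim(grid_like)))
    stop("partition grid does not match mask dimensions", call. = FALSE)
}

#' Per-cell IoU of a prediction against the ground truth
#'
#' Element \eqn{i} is the IoU of the prediction and the ground truth
#' restricted to cell \eqn{i} of the partition. Cells where both masks are
#' empty score 0 by the empty-empty convention (they always carry
#' \eqn{\delta_i = 0}, so the convention never reaches the loss).
#'
#' @param pred,gt masks on the same grid.
#' @param part a [partition_grid()] result on that grid.
#' @return Numeric vector of length \code{part$k}, values in \[0, 1\].
#' @export
per_part_iou <- function(pred, gt, part) {
  .assert_mask(pred, "pred"); .assert_mask(gt, "gt")
  .assert_same_dim(pred, gt)
  .assert_partition(part, gt)
  cellv <- as.vector(part$cell)
  k <- part$k
  if (is.logical(pred) && is.logical(gt)) {
    inter <- tabulate(cellv[as.vector(pred & gt)], nbins = k)
    uni <- tabulate(cellv[as.vector(pred | gt)], nbins = k)
  } else {
    p <- as.vector(pred * 1); g <- as.vector(gt * 1)
    inter <- .fill_by_group(p * g, cellv, k)
    uni <- .fill_by_group(p + g - p * g, cellv, k)
  }
  ifelse(uni > 0, inter / uni, 0)
}

.fill_by_group <- function(x, g, k) {
  out <- numeric(k)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
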