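# File formats. Masks travel as COCO-dialect uncompressed RLE: counts of
# alternating background/foreground runs over the pixels taken in
# column-major (Fortran) order, always starting with a background count
# (possibly 0). One convention, stated here, used everywhere.

#' Run-length encode a binary mask (COCO dialect)
#'
#' @param m logical mask.
#' @return Integer vector of run counts, column-major, starting with the
#'   background run (0 if the first pixel is foreground).
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE
#' rle_encode(m)  # 0 1 8
#' @export
rle_encode <- function(m) {
  .assert_mask(m)
  v <- as.integer(as.vector(m))  # R matrices are column-major already
  r <- rle(v)
  counts <- r$lengths
  if (length(v) == 0) return(integer(0))
  if (r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

#' Decode a COCO-dialect run-length encoding
#'
#' @param counts integer run counts (see [rle_encode()]).
#' @param height,width mask dimensions; \code{sum(counts)} must equal
#'   \code{height * width}.
#' @return Logical mask.
#' @export
rle_decode <- function(counts, height, width) {
  counts <- as.integer(counts)
  if (any(counts < 0) || anyNA(counts))
    stop("RLE counts must be non-negative integers", call. = FALSE)
  if (sum(counts) != height * width)
    stop(sprintf("RLE length mismatch: counts sum to %d, image has %d pixels",
                 sum(counts), height * width), call. = FALSE)
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  matrix(vals, nrow = height, ncol = width)
}

#' Bundle scenes for serialization
#'
#' A dataset bundle collects images (as metadata plus optional pixel
#' data), per-image ground-truth instances and per-image detections, with
#' free-form provenance metadata. [write_coco_json()] serializes it.
#'
#' @param scenes list of [generate_scene()] scenes (detections optional).
#' @param metadata named list of provenance fields (seed, config hash, ...).
#' @return Object of class \code{"dataset_bundle"}.
#' @export
dataset_bundle <- function(scenes, metadata = list()) {
  if (inherits(scenes, "chromosome_scene")) scenes <- list(scenes)
  stopifnot(all(vapply(scenes, inherits, logical(1), "chromosome_scene")))
  images <- lapply(seq_along(scenes), function(i) {
    list(id = i, height = nrow(scenes[[i]]$image),
         width = ncol(scenes[[i]]$image))
  })
  gt <- lapply(scenes, function(s) list(masks = s$gt_masks, boxes = s$gt_boxes))
  dets <- lapply(seq_along(scenes), function(i) {
    d <- scenes[[i]]$detections
    if (is.null(d)) return(list())
    lapply(d, function(x) { x$image_id <- i; x })
  })
  metadata$tool <- "chromseg"
  metadata$version <- as.character(utils::packageVersion("chromseg"))
  structure(list(images = images, gt = gt, detections = dets,
                 pixels = lapply(scenes, `[[`, "image"),
                 metadata = metadata),
            class = "dataset_bundle")
}

.box_to_coco <- function(b) {
  c(b[["x1"]], b[["y1"]], b[["x2"]] - b[["x1"]], b[["y2"]] - b[["y1"]])
}

.coco_to_box <- function(v) box(v[1], v[2], v[1] + v[3], v[2] + v[4])

#' Write a dataset bundle as COCO-style instance JSON
#'
#' Standard COCO layout (\code{images}, \code{annotations},
#' \code{categories}, single category \code{chromosome}) with masks as
#' uncompressed column-major RLE, plus a \code{detections} results array
#' carrying the raw confidence and the auxiliary-head outputs alongside
#' the corrected \code{score} (the raw value is never overwritten), and a
#' \code{metadata} block. The round trip through [read_coco_json()] is
#' lossless for masks, boxes and scores. Pixel data is not stored.
#'
#' @param bundle a [dataset_bundle()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_coco_json <- function(bundle, path) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  ann <- list(); aid <- 0L
  for (i in seq_along(bundle$gt)) {
    hw <- c(bundle$images[[i]]$height, bundle$images[[i]]$width)
    for (j in seq_along(bundle$gt[[i]]$masks)) {
      aid <- aid + 1L
      m <- bundle$gt[[i]]$masks[[j]]
      ann[[aid]] <- list(
        id = aid, image_id = i, category_id = 1L,
        segmentation = list(size = hw, counts = rle_encode(m)),
        bbox = .box_to_coco(bundle$gt[[i]]$boxes[[j]]),
        area = sum(m), iscrowd = 0L)
    }
  }
  det <- list(); k <- 0L
  for (i in seq_along(bundle$detections)) {
    hw <- c(bundle$images[[i]]$height, bundle$images[[i]]$width)
    for (d in bundle$detections[[i]]) {
      k <- k + 1L
      det[[k]] <- list(
        image_id = i, category_id = 1L, instance_id = d$instance_id,
        segmentation = list(size = hw, counts = rle_encode(d$mask)),
        bbox = .box_to_coco(d$box),
        score = d$score, p_cls = d$p_cls, p_box = d$p_box,
        iou_mask = d$iou_mask)
    }
  }
  out <- list(
    images = lapply(bundle$images, function(im)
      c(im, list(file_name = sprintf("scene_%03d.png", im$id)))),
    annotations = ann,
    categories = list(list(id = 1L, name = "chromosome",
                           supercategory = "cell")),
    detections = det,
    metadata = bundle$metadata)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.decode_segmentation <- function(seg, rec_id) {
  size <- unlist(seg$size)
  counts <- unlist(seg$counts)
  if (length(size) != 2)
    stop(sprintf("record %s: malformed RLE size", rec_id), call. = FALSE)
  tryCatch(rle_decode(counts, size[1], size[2]),
           error = function(e)
             stop(sprintf("record %s: %s", rec_id, conditionMessage(e)),
                  call. = FALSE))
}

#' Read a COCO-style instance JSON back into a bundle-like list
#'
#' Validates referential integrity (every annotation and detection must
#' name a known image) and RLE lengths, reporting the offending record id
#' on failure.
#'
#' @param path JSON file written by [write_coco_json()] (or compatible).
#' @return List of class \code{"dataset_bundle"} with \code{images},
#'   \code{gt} (masks and boxes per image), \code{detections}
#'   ([detection()] lists per image) and \code{metadata}; pixel data is
#'   \code{NULL}.
#' @export
read_coco_json <- function(path) {
  x <- jsonlite::read_json(path)
  images <- lapply(x$images, function(im)
    list(id = im$id, height = im$height, width = im$width))
  ids <- vapply(images, `[[`, numeric(1), "id")
  img_index <- stats::setNames(seq_along(ids), ids)

  gt <- lapply(images, function(im) list(masks = list(), boxes = list()))
  for (a in x$annotations) {
    key <- as.character(a$image_id)
    if (is.na(img_index[key]))
      stop(sprintf("annotation %s references unknown image id %s",
                   a$id, a$image_id), call. = FALSE)
    i <- img_index[[key]]
    m <- .decode_segmentation(a$segmentation, paste0("annotation ", a$id))
    gt[[i]]$masks <- c(gt[[i]]$masks, list(m))
    gt[[i]]$boxes <- c(gt[[i]]$boxes, list(.coco_to_box(unlist(a$bbox))))
  }

  dets <- lapply(images, function(im) list())
  for (d in x$detections) {
    key <- as.character(d$image_id)
    if (is.na(img_index[key]))
      stop(sprintf("detection (instance %s) references unknown image id %s",
                   d$instance_id, d$image_id), call. = FALSE)
    i <- img_index[[key]]
    m <- .decode_segmentation(d$segmentation,
                              paste0("detection ", d$instance_id))
    dd <- detection(.coco_to_box(unlist(d$bbox)), m,
                    p_cls = d$p_cls,
                    p_box = if (is.null(d$p_box)) NA_real_ else d$p_box,
                    iou_mask = if (is.null(d$iou_mask)) NA_real_ else d$iou_mask,
                    score = if (is.null(d$score)) NA_real_ else d$score,
                    instance_id = d$instance_id, image_id = i)
    dets[[i]] <- c(dets[[i]], list(dd))
  }

  structure(list(images = images, gt = gt, detections = dets,
                 pixels = NULL, metadata = x$metadata),
            class = "dataset_bundle")
}

#' Write instance masks as a label PNG
#'
#' Background is 0 and instance \code{i} carries label \code{i}. Labels up
#' to 65,535 are stored losslessly by splitting each id across two 8-bit
#' channels of an RGB PNG (red = high byte, green = low byte). A single
#' label map cannot represent overlapping instances: by default an
#' explicit error points to per-instance mode
#' (\code{per_instance = TRUE}), which writes one file per mask with an
#' \code{_instNNN} suffix.
#'
#' @param masks list of logical masks (possibly empty).
#' @param path output path; base name for per-instance mode.
#' @param per_instance write one PNG per instance instead of a single map.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_label_png <- function(masks, path, per_instance = FALSE) {
  stopifnot(is.list(masks))
  if (length(masks) > 65535L) stop("more than 65535 instances", call. = FALSE)
  lapply(masks, .assert_mask)
  if (length(masks) > 0) {
    dims <- vapply(masks, dim, integer(2))
    if (any(dims != dims[, 1])) stop("mask dimensions differ", call. = FALSE)
    h <- dims[1, 1]; w <- dims[2, 1]
  } else {
    h <- 1L; w <- 1L
  }
  encode <- function(lab) {
    arr <- array(0, dim = c(h, w, 3))
    arr[, , 1] <- (lab %/% 256L) / 255
    arr[, , 2] <- (lab %% 256L) / 255
    arr
  }
  if (per_instance) {
    files <- character(length(masks))
    stem <- sub("\\.png$", "", path)
    for (i in seq_along(masks)) {
      lab <- matrix(0L, h, w)
      lab[masks[[i]]] <- i
      files[i] <- sprintf("%s_inst%03d.png", stem, i)
      png::writePNG(encode(lab), files[i])
    }
    return(invisible(files))
  }
  lab <- matrix(0L, h, w)
  for (i in seq_along(masks)) {
    if (any(lab[masks[[i]]] != 0L))
      stop("instances overlap: a single label map cannot represent them; ",
           "use per_instance = TRUE", call. = FALSE)
    lab[masks[[i]]] <- i
  }
  png::writePNG(encode(lab), path)
  invisible(path)
}

#' Read a label PNG back into instance masks
#'
#' @param path file(s) written by [write_label_png()]; a vector of paths
#'   is read as per-instance maps and merged.
#' @return List of logical masks, one per instance label present.
#' @export
read_label_png <- function(path) {
  read_one <- function(p) {
    arr <- png::readPNG(p)
    if (length(dim(arr)) == 2) return(matrix(as.integer(round(arr * 255)),
                                             nrow(arr), ncol(arr)))
    round(arr[, , 1] * 255) * 256L + round(arr[, , 2] * 255)
  }
  if (length(path) == 1) {
    lab <- read_one(path)
    labels <- sort(setdiff(unique(as.vector(lab)), 0))
    return(lapply(labels, function(l) lab == l))
  }
  masks <- list()
  for (p in path) {
    lab <- read_one(p)
    for (l in sort(setdiff(unique(as.vector(lab)), 0)))
      masks[[l]] <- lab == l
  }
  masks
}

#' Write / read a flat CSV detection table
#'
#' Columns: \code{image_id, instance_id, x1, y1, x2, y2, p_cls, p_box,
#' iou_mask, score}. Masks are not carried; the CSV is the light-weight
#' companion of the COCO JSON for spreadsheet-level inspection.
#'
#' @param dets list of detections (any mix of images).
#' @param path CSV path.
#' @return For the writer, \code{path} invisibly; for the reader, a
#'   data.frame.
#' @export
write_detections_csv <- function(dets, path) {
  .assert_detections_any_grid(dets)
  df <- do.call(rbind, lapply(dets, function(d) {
    data.frame(image_id = d$image_id, instance_id = d$instance_id,
               x1 = d$box[["x1"]], y1 = d$box[["y1"]],
               x2 = d$box[["x2"]], y2 = d$box[["y2"]],
               p_cls = d$p_cls, p_box = d$p_box,
               iou_mask = d$iou_mask, score = d$score)
  }))
  if (is.null(df)) df <- data.frame(image_id = integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.assert_detections_any_grid <- function(dets) {
  if (!is.list(dets) || !all(vapply(dets, is_detection, logical(1))))
    stop("`dets` must be a list of detection() objects", call. = FALSE)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  utils::read.csv(path)
}
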