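# Anchor-based box decoding and non-maximum suppression.
#
# Raw head outputs are (na*(nc+5), H, W, N) maps per scale.  Decoding uses
# the standard v5 transform: xy = (2*sigmoid - 0.5 + grid) / grid_size,
# wh = (2*sigmoid)^2 * anchor / input_size, confidence = obj * class.

decode_head <- function(raw, anchors, input_size, n_classes, img_index = 1L) {
  d <- dim(raw)
  na <- nrow(anchors)
  step <- n_classes + 5L
  Hg <- d[2]; Wg <- d[3]
  out <- vector("list", na)
  gx <- matrix(rep(0:(Wg - 1L), each = Hg), Hg)   # column index per cell
  gy <- matrix(rep(0:(Hg - 1L), Wg), Hg)
  for (a in seq_len(na)) {
    base <- (a - 1L) * step
    sl <- function(k) {
      m <- raw[base + k, , , img_index]
      1 / (1 + exp(-m))
    }
    cx <- (2 * sl(1) - 0.5 + gx) / Wg
    cy <- (2 * sl(2) - 0.5 + gy) / Hg
    w <- (2 * sl(3))^2 * anchors[a, 1] / input_size
    h <- (2 * sl(4))^2 * anchors[a, 2] / input_size
    obj <- sl(5)
    if (n_classes == 1L) {
      cls_p <- sl(6)
      cls_id <- matrix(0L, Hg, Wg)
    } else {
      probs <- vapply(seq_len(n_classes), function(k) sl(5 + k),
                      matrix(0, Hg, Wg))
      cls_p <- apply(probs, c(1, 2), max)
      cls_id <- apply(probs, c(1, 2), which.max) - 1L
    }
    out[[a]] <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
                           w = as.numeric(w), h = as.numeric(h),
                           conf = as.numeric(obj * cls_p),
                           class = as.integer(cls_id))
  }
  do.call(rbind, out)
}

#' Greedy non-maximum suppression
#'
#' @param dets detection data.frame (`cx, cy, w, h, conf`)
#' @param iou_thresh suppression threshold
#' @return the surviving rows, confidence-descending
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  dets <- as_det_df(dets)
  if (!nrow(dets)) return(dets)
  ord <- order(-dets$conf)
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  boxes <- as.matrix(dets[, c("cx", "cy", "w", "h")])
  alive <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(dets)) {
      rest <- which(alive & seq_len(nrow(dets)) > i)
      if (length(rest)) {
        iou <- box_iou(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
        alive[rest[iou[1, ] >= iou_thresh]] <- FALSE
      }
    }
  }
  dets[keep, , drop = FALSE]
}

#' Run detection on one rendered image
#'
#' @param model a built detector (see [build_model()])
#' @param image array `H x W x 3` in [0,1], sized to the model's
#'   `input_size`
#' @param conf_thresh confidence threshold
#' @param iou_thresh NMS IoU threshold
#' @return data.frame `cx, cy, w, h, conf, class` (normalized coordinates)
#' @export
detect <- function(model, image, conf_thresh = 0.25, iou_thresh = 0.45) {
  d <- dim(image)
  sz <- model$cfg$input_size
  if (length(d) != 3 || d[1] != sz || d[2] != sz)
    stop(sprintf("image must be %d x %d x 3 for this model", sz, sz))
  x <- aperm(image, c(3, 1, 2))
  dim(x) <- c(3L, sz, sz, 1L)
  outs <- yb_no_grad(model$forward(yb_tensor(x), training = FALSE))
  dets <- do.call(rbind, lapply(seq_along(outs), function(s)
    decode_head(outs[[s]]$v, model$cfg$anchors[[s]], sz,
                model$cfg$n_classes)))
  dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
  if (!nrow(dets)) return(dets)
  nms(dets, iou_thresh)
}

#' Estimate anchors from training boxes by k-means
#'
#' Bad-trial boxes are tall and narrow (full height, one-tenth width),
#' unlike natural-image priors, so anchors are re-estimated from the data.
#'
#' @param boxes_wh matrix of box (w, h) in pixels at the input size
#' @param n_anchors total anchors (3 per scale)
#' @return anchor list as in [default_anchors()], sorted by area
#' @export
kmeans_anchors <- function(boxes_wh, n_anchors = 9L) {
  boxes_wh <- rbind(boxes_wh)
  uniq <- unique(boxes_wh)
  if (nrow(uniq) < n_anchors) {
    jit <- boxes_wh[sample(nrow(boxes_wh), n_anchors, replace = TRUE), ,
                    drop = FALSE]
    jit <- jit * matrix(stats::runif(2 * n_anchors, 0.85, 1.15),
                        n_anchors)
    centers <- jit
  } else {
    centers <- stats::kmeans(boxes_wh, centers = n_anchors,
                             nstart = 5)$centers
  }
  centers <- centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
  list(p3 = centers[1:3, , drop = FALSE],
       p4 = centers[4:6, , drop = FALSE],
       p5 = centers[7:9, , drop = FALSE])
}
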