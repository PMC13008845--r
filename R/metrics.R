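# Detection evaluation: precision/recall, AP by explicit threshold sweep,
# mAP, F1, and the severity-stratified report.
#
#   Precision = TP / (TP + FP)        Recall = TP / (TP + FN)
#   AP  = sum_n (R(n) - R(n-1)) P(n)  over the descending-confidence sweep
#   mAP = mean over classes            F1 = 2PR / (P + R)
#
# Zero denominators return 0 (with a warning for P/R).  AP uses the sum
# exactly as written, with no interpolation by default; 11-point and
# 101-point interpolated variants are available for comparison.

#' Intersection-over-union of two box sets
#'
#' @param a,b matrices with columns `cx, cy, w, h` (normalized or pixel
#'   units, as long as both agree)
#' @return `nrow(a) x nrow(b)` IoU matrix
#' @export
box_iou <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  out <- matrix(0, nrow(a), nrow(b))
  ax1 <- a[, 1] - a[, 3] / 2; ax2 <- a[, 1] + a[, 3] / 2
  ay1 <- a[, 2] - a[, 4] / 2; ay2 <- a[, 2] + a[, 4] / 2
  bx1 <- b[, 1] - b[, 3] / 2; bx2 <- b[, 1] + b[, 3] / 2
  by1 <- b[, 2] - b[, 4] / 2; by2 <- b[, 2] + b[, 4] / 2
  for (i in seq_len(nrow(a))) {
    iw <- pmax(0, pmin(ax2[i], bx2) - pmax(ax1[i], bx1))
    ih <- pmax(0, pmin(ay2[i], by2) - pmax(ay1[i], by1))
    inter <- iw * ih
    uni <- (ax2[i] - ax1[i]) * (ay2[i] - ay1[i]) +
      (bx2 - bx1) * (by2 - by1) - inter
    out[i, ] <- ifelse(uni > 0, inter / uni, 0)
  }
  out
}

as_det_df <- function(dets) {
  if (is.null(dets) || (is.data.frame(dets) && !nrow(dets)) ||
      (is.matrix(dets) && !nrow(dets)))
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), conf = numeric()))
  df <- as.data.frame(dets)
  need <- c("cx", "cy", "w", "h", "conf")
  if (!all(need %in% names(df))) stop("detections need columns cx,cy,w,h,conf")
  if (any(df$conf < 0 | df$conf > 1)) stop("confidences must lie in [0,1]")
  df
}

#' Match detections to ground truth
#'
#' Detections are taken in descending confidence order; each matches the
#' highest-IoU still-unmatched truth with IoU >= `iou_thresh` (a true
#' positive), otherwise it is a false positive.  Unmatched truths are
#' false negatives.
#'
#' @param dets data.frame with `cx, cy, w, h, conf`
#' @param truths box matrix with columns including `cx, cy, w, h`
#' @param iou_thresh matching threshold
#' @return list with `TP`, `FP`, `FN`, and `det_tp` (logical per detection,
#'   in the original row order)
#' @export
match_detections <- function(dets, truths, iou_thresh = 0.5) {
  dets <- as_det_df(dets)
  tb <- truth_boxes(truths)
  nt <- nrow(tb)
  nd <- nrow(dets)
  det_tp <- logical(nd)
  det_truth <- rep(NA_integer_, nd)
  if (nd > 0 && nt > 0) {
    ord <- order(-dets$conf)
    used <- logical(nt)
    iou <- box_iou(as.matrix(dets[, c("cx", "cy", "w", "h")]), tb)
    for (i in ord) {
      cand <- which(!used & iou[i, ] >= iou_thresh)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        det_tp[i] <- TRUE
        det_truth[i] <- j
      }
    }
  }
  tp <- sum(det_tp)
  list(TP = tp, FP = nd - tp, FN = nt - tp, det_tp = det_tp,
       det_truth = det_truth)
}

truth_boxes <- function(truths) {
  if (is.null(truths) || !length(truths))
    return(matrix(0, 0, 4))
  tb <- rbind(truths)
  cols <- colnames(tb)
  if (!is.null(cols) && all(c("cx", "cy", "w", "h") %in% cols))
    tb <- tb[, c("cx", "cy", "w", "h"), drop = FALSE]
  else if (ncol(tb) == 5) tb <- tb[, 2:5, drop = FALSE]
  tb
}

#' Precision and recall from match counts
#'
#' @param counts list with `TP`, `FP`, `FN`
#' @return named vector `precision`, `recall`; zero denominators give 0
#' @export
precision_recall <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  p <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no detections: precision defined as 0"); 0
  }
  r <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no ground truths: recall defined as 0"); 0
  }
  c(precision = p, recall = r)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' Scale-symmetric: fractional inputs give a fraction, percent inputs give
#' a percent.
#'
#' @param p,r precision and recall
#' @return `2 p r / (p + r)`, or 0 when both are 0
#' @export
f1_score <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Average precision by explicit confidence-threshold sweep
#'
#' Sweeps the distinct detection confidences in descending order and
#' accumulates `sum_n (R(n) - R(n-1)) P(n)`.  `interpolation` selects the
#' optional interpolated variants.
#'
#' @param det_tp logical vector: is each detection a true positive?
#' @param conf detection confidences
#' @param n_truth total number of ground-truth boxes
#' @param interpolation "none" (the printed sum), "11point" or "101point"
#' @return list with `ap` and the `precision`/`recall`/`threshold` series
#' @export
average_precision <- function(det_tp, conf, n_truth,
                              interpolation = c("none", "11point",
                                                "101point")) {
  interpolation <- match.arg(interpolation)
  if (n_truth == 0) return(list(ap = 0, precision = numeric(),
                                recall = numeric(), threshold = numeric()))
  if (!length(conf))
    return(list(ap = 0, precision = numeric(), recall = numeric(),
                threshold = numeric()))
  thr <- sort(unique(conf), decreasing = TRUE)
  P <- R <- numeric(length(thr))
  for (i in seq_along(thr)) {
    keep <- conf >= thr[i]
    tp <- sum(det_tp[keep])
    P[i] <- tp / sum(keep)
    R[i] <- tp / n_truth
  }
  ap <- switch(interpolation,
    none = sum(diff(c(0, R)) * P),
    `11point` = {
      rr <- seq(0, 1, by = 0.1)
      mean(vapply(rr, function(t) {
        ok <- R >= t
        if (any(ok)) max(P[ok]) else 0
      }, 0))
    },
    `101point` = {
      rr <- seq(0, 1, by = 0.01)
      mean(vapply(rr, function(t) {
        ok <- R >= t
        if (any(ok)) max(P[ok]) else 0
      }, 0))
    })
  list(ap = ap, precision = P, recall = R, threshold = thr)
}

#' Mean average precision over classes
#' @param aps numeric vector of per-class APs
#' @return their arithmetic mean
#' @export
mean_ap <- function(aps) {
  if (!length(aps)) stop("need at least one class AP")
  mean(aps)
}

#' Evaluate detections over a dataset
#'
#' Matches per image at `iou_thresh`, pools the detections for the AP
#' sweep, and reports precision/recall/F1 at `conf_thresh` plus AP (the
#' single-class mAP).
#'
#' @param det_list list (one per image) of detection data.frames
#' @param truth_list list (one per image) of truth box matrices
#' @param iou_thresh IoU matching threshold
#' @param conf_thresh operating confidence for P/R/F1
#' @param interpolation AP variant, see [average_precision()]
#' @return list: `precision`, `recall`, `f1`, `ap`, `map`, `counts`, `pr`
#' @export
evaluate_detections <- function(det_list, truth_list, iou_thresh = 0.5,
                                conf_thresh = 0.25,
                                interpolation = "none") {
  stopifnot(length(det_list) == length(truth_list))
  all_tp <- logical(0); all_conf <- numeric(0)
  n_truth <- 0L
  tp_op <- fp_op <- fn_op <- 0L
  for (i in seq_along(det_list)) {
    dets <- as_det_df(det_list[[i]])
    m <- match_detections(dets, truth_list[[i]], iou_thresh)
    all_tp <- c(all_tp, m$det_tp)
    all_conf <- c(all_conf, dets$conf)
    n_truth <- n_truth + nrow(truth_boxes(truth_list[[i]]))
    keep <- dets$conf >= conf_thresh
    mo <- match_detections(dets[keep, , drop = FALSE], truth_list[[i]],
                           iou_thresh)
    tp_op <- tp_op + mo$TP; fp_op <- fp_op + mo$FP; fn_op <- fn_op + mo$FN
  }
  pr <- suppressWarnings(
    precision_recall(list(TP = tp_op, FP = fp_op, FN = fn_op)))
  apr <- average_precision(all_tp, all_conf, n_truth, interpolation)
  list(precision = pr[["precision"]], recall = pr[["recall"]],
       f1 = f1_score(pr[["precision"]], pr[["recall"]]),
       ap = apr$ap, map = mean_ap(apr$ap),
       counts = list(TP = tp_op, FP = fp_op, FN = fn_op),
       pr = apr)
}

#' Severity-stratified evaluation report
#'
#' Assigns every trial to a stratum from its Max PTP and the screen's bad
#' channels -- severe (> 3000), moderate (500, 3000], bad-channel
#' interference (<= 500 with at least one bad channel), clean otherwise --
#' and reports P/R/F1 within each stratum plus overall.  Detections are
#' assigned to the trial containing their box center.
#'
#' @param screens list of `eeg_screen`s with `trial_stats`
#' @param det_list list (one per screen) of detection data.frames
#' @param iou_thresh IoU threshold for counting a detection as correct
#' @param conf_thresh operating confidence
#' @param bands a [severity_bands()]
#' @return list with `strata` (data.frame) and `overall`
#' @export
stratified_report <- function(screens, det_list, iou_thresh = 0.5,
                              conf_thresh = 0.25,
                              bands = severity_bands()) {
  stopifnot(length(screens) == length(det_list))
  strata <- c("severe", "moderate", "bad_channel_interference", "clean")
  cnt <- matrix(0L, length(strata), 3,
                dimnames = list(strata, c("TP", "FP", "FN")))
  n_trials <- integer(length(strata)); names(n_trials) <- strata
  for (i in seq_along(screens)) {
    scr <- screens[[i]]
    if (is.null(scr$trial_stats)) stop("screen ", i, " lacks trial_stats")
    Tn <- length(scr$trial_labels)
    ptp <- scr$trial_stats$max_ptp
    has_bad <- any(scr$bad_channel_mask)
    stratum <- ifelse(ptp > bands$severe_low, "severe",
               ifelse(ptp > bands$moderate_low, "moderate",
               ifelse(has_bad, "bad_channel_interference", "clean")))
    for (s in strata) n_trials[s] <- n_trials[s] + sum(stratum == s)
    dets <- as_det_df(det_list[[i]])
    dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
    truths <- boxes_for_bad_trials(scr)
    m <- match_detections(dets, truths, iou_thresh)
    bad_idx <- which(scr$trial_labels)
    # detection -> trial by box-center column
    det_trial <- pmin(Tn, pmax(1L, 1L + floor(dets$cx * Tn)))
    for (j in seq_len(nrow(dets))) {
      s <- stratum[det_trial[j]]
      if (m$det_tp[j]) cnt[s, "TP"] <- cnt[s, "TP"] + 1L
      else cnt[s, "FP"] <- cnt[s, "FP"] + 1L
    }
    missed <- setdiff(seq_along(bad_idx),
                      m$det_truth[!is.na(m$det_truth)])
    for (j in missed) {
      s <- stratum[bad_idx[j]]
      cnt[s, "FN"] <- cnt[s, "FN"] + 1L
    }
  }
  per <- data.frame(stratum = strata, n_trials = as.integer(n_trials),
                    TP = cnt[, "TP"], FP = cnt[, "FP"], FN = cnt[, "FN"])
  pr <- t(apply(cnt, 1, function(r) {
    p <- if (r["TP"] + r["FP"] > 0) r["TP"] / (r["TP"] + r["FP"]) else 0
    rc <- if (r["TP"] + r["FN"] > 0) r["TP"] / (r["TP"] + r["FN"]) else 0
    c(precision = p, recall = rc, f1 = f1_score(p, rc))
  }))
  per <- cbind(per, pr)
  tot <- colSums(cnt)
  p <- if (tot["TP"] + tot["FP"] > 0) tot["TP"] / (tot["TP"] + tot["FP"]) else 0
  r <- if (tot["TP"] + tot["FN"] > 0) tot["TP"] / (tot["TP"] + tot["FN"]) else 0
  list(strata = per,
       overall = c(precision = unname(p), recall = unname(r),
                   f1 = unname(f1_score(p, r))))
}
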