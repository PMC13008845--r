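# Training: composite detection loss (CIoU box + BCE objectness [+ BCE
# class]), center-cell anchor assignment with a wh-ratio filter, SGD with
# momentum, weight decay and cosine-annealed learning rate, mosaic/mixup
# augmentation, early stopping on validation mAP and best-checkpoint
# return.

#' Training configuration
#'
#' Defaults follow the standard recipe: 600 epochs with early-stopping
#' patience 50, batch 16, SGD(momentum 0.937), initial lr 0.01 cosine-
#' annealed to `lr0 * lrf`, weight decay 5e-4, mosaic + mixup(alpha 0.2).
#'
#' @param epochs maximum epochs
#' @param patience early-stopping patience on validation mAP
#' @param batch_size images per step
#' @param lr0 initial learning rate
#' @param lrf final lr as a fraction of `lr0`
#' @param momentum SGD momentum
#' @param weight_decay decoupled weight decay on conv/dense weights
#' @param warmup_epochs linear lr warmup epochs
#' @param mosaic use 4-image mosaic augmentation?
#' @param mixup_alpha Beta parameter for mixup (0 disables)
#' @param box_gain,obj_gain,cls_gain loss component weights
#' @param auto_anchors re-estimate anchors from the training boxes?
#' @param conf_thresh,iou_thresh evaluation settings during training
#' @param seed RNG seed for the whole run
#' @return a `train_config` object
#' @export
train_config <- function(epochs = 600L, patience = 50L, batch_size = 16L,
                         lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                         weight_decay = 5e-4, warmup_epochs = 0L,
                         mosaic = TRUE, mixup_alpha = 0.2,
                         box_gain = 0.05, obj_gain = 1.0, cls_gain = 0.5,
                         auto_anchors = TRUE, conf_thresh = 0.25,
                         iou_thresh = 0.45, obj_target = c("iou", "one"),
                         seed = 0L) {
  stopifnot(epochs > 0, batch_size > 0, lr0 > 0, patience > 0)
  obj_target <- match.arg(obj_target)
  structure(as.list(environment()), class = "train_config")
}

# ---- target assignment --------------------------------------------------

# boxes: matrix (class,cx,cy,w,h) normalized; returns per-scale data.frames
build_targets <- function(boxes_list, grids, anchors_px, input_size,
                          ratio_thresh = 4) {
  ns <- length(grids)
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    Hg <- grids[[s]][1]; Wg <- grids[[s]][2]
    stride <- input_size / Wg
    ag <- anchors_px[[s]] / stride
    rows <- list()
    for (n in seq_along(boxes_list)) {
      bx <- boxes_list[[n]]
      if (is.null(bx) || !nrow(bx)) next
      for (bi in seq_len(nrow(bx))) {
        gx <- bx[bi, "cx"] * Wg; gy <- bx[bi, "cy"] * Hg
        tw <- max(bx[bi, "w"] * Wg, 1e-4)
        th <- max(bx[bi, "h"] * Hg, 1e-4)
        j0 <- min(Wg - 1L, max(0L, floor(gx)))
        i0 <- min(Hg - 1L, max(0L, floor(gy)))
        # the center cell plus the two nearest neighbours (offsets within
        # the 2*sigmoid - 0.5 decode range) for extra positive samples
        cells <- list(c(i0, j0))
        fx <- gx - j0; fy <- gy - i0
        jn <- j0 + if (fx < 0.5) -1L else 1L
        ifn <- i0 + if (fy < 0.5) -1L else 1L
        if (jn >= 0L && jn < Wg) cells <- c(cells, list(c(i0, jn)))
        if (ifn >= 0L && ifn < Hg) cells <- c(cells, list(c(ifn, j0)))
        for (cell in cells) {
          i <- cell[1]; j <- cell[2]
          tx <- gx - j; ty <- gy - i
          if (tx < -0.5 || tx > 1.5 || ty < -0.5 || ty > 1.5) next
          for (a in seq_len(nrow(ag))) {
            r <- max(tw / ag[a, 1], ag[a, 1] / tw, th / ag[a, 2],
                     ag[a, 2] / th)
            if (r < ratio_thresh)
              rows[[length(rows) + 1L]] <-
                c(n = n, a = a, i = i, j = j, tx = tx, ty = ty,
                  tw = tw, th = th, aw = ag[a, 1], ah = ag[a, 2],
                  cls = bx[bi, "class"])
          }
        }
      }
    }
    out[s] <- list(if (length(rows)) as.data.frame(do.call(rbind, rows))
                   else NULL)
  }
  out
}

# differentiable complete-IoU between predicted and target boxes (grid
# units, cell-corner origin); alpha is treated as a constant, as usual
ciou_tensor <- function(px, py, pw, ph, tg) {
  ct <- function(v) yb_tensor(matrix(v, ncol = 1))
  tx <- ct(tg$tx); ty <- ct(tg$ty); tw <- ct(tg$tw); th <- ct(tg$th)
  half <- function(w) op_affine(w, 0.5)
  pr <- op_add(px, half(pw)); pl <- op_sub(px, half(pw))
  pt <- op_sub(py, half(ph)); pb <- op_add(py, half(ph))
  tr <- op_add(tx, half(tw)); tl <- op_sub(tx, half(tw))
  tt <- op_sub(ty, half(th)); tb <- op_add(ty, half(th))
  iw <- op_relu(op_sub(op_pmin(pr, tr), op_pmax(pl, tl)))
  ih <- op_relu(op_sub(op_pmin(pb, tb), op_pmax(pt, tt)))
  inter <- op_mul(iw, ih)
  uni <- op_affine(op_sub(op_add(op_mul(pw, ph), op_mul(tw, th)), inter),
                   1, 1e-9)
  iou <- op_div(inter, uni)
  d2 <- op_add(op_square(op_sub(px, tx)), op_square(op_sub(py, ty)))
  cw <- op_sub(op_pmax(pr, tr), op_pmin(pl, tl))
  chh <- op_sub(op_pmax(pb, tb), op_pmin(pt, tt))
  c2 <- op_affine(op_add(op_square(cw), op_square(chh)), 1, 1e-9)
  vterm <- op_square(op_sub(op_atan(op_div(tw, th)),
                            op_atan(op_div(pw, ph))))
  vterm <- op_affine(vterm, 4 / pi^2)
  alpha <- vterm$v / (1 - iou$v + vterm$v + 1e-9)   # detached
  op_sub(op_sub(iou, op_div(d2, c2)), op_mul(vterm, yb_tensor(alpha)))
}

flat_cells <- function(C, Hg, Wg, N) {
  hh <- rep(0:(Hg - 1L), times = Wg * N)
  ww <- rep(rep(0:(Wg - 1L), each = Hg), times = N)
  nn <- rep(0:(N - 1L), each = Hg * Wg)
  hh * C + ww * C * Hg + nn * C * Hg * Wg
}

# loss over one batch; outs: raw head tensors, boxes_list: per-image truth
compute_loss <- function(outs, boxes_list, cfg, anchors_px, input_size,
                         n_classes) {
  grids <- lapply(outs, function(o) dim(o$v)[2:3])
  tg <- build_targets(boxes_list, grids, anchors_px, input_size)
  N <- dim(outs[[1]]$v)[4]
  na <- nrow(anchors_px[[1]])
  step <- n_classes + 5L
  balance <- c(4.0, 1.0, 0.4)
  total <- NULL
  add_term <- function(tot, t) if (is.null(tot)) t else op_add(tot, t)
  n_pos_total <- 0L
  box_sum <- NULL
  for (s in seq_along(outs)) {
    o <- outs[[s]]
    C <- dim(o$v)[1]; Hg <- dim(o$v)[2]; Wg <- dim(o$v)[3]
    cells <- flat_cells(C, Hg, Wg, N)
    obj_idx <- unlist(lapply(seq_len(na), function(a)
      (a - 1L) * step + 5L + cells))
    obj_t <- numeric(length(obj_idx))
    t <- tg[[s]]
    if (!is.null(t) && nrow(t)) {
      cell_flat <- function(ch) ch + t$i * C + t$j * C * Hg +
        (t$n - 1) * C * Hg * Wg
      base <- (t$a - 1L) * step
      px <- op_affine(op_sigmoid(op_gather(o, cell_flat(base + 1L))),
                      2, -0.5)
      py <- op_affine(op_sigmoid(op_gather(o, cell_flat(base + 2L))),
                      2, -0.5)
      pw <- op_mul(op_square(op_affine(
        op_sigmoid(op_gather(o, cell_flat(base + 3L))), 2)),
        yb_tensor(matrix(t$aw, ncol = 1)))
      ph <- op_mul(op_square(op_affine(
        op_sigmoid(op_gather(o, cell_flat(base + 4L))), 2)),
        yb_tensor(matrix(t$ah, ncol = 1)))
      ciou <- ciou_tensor(px, py, pw, ph, t)
      box_sum <- add_term(box_sum, op_sum(op_affine(ciou, -1, 1)))
      n_pos_total <- n_pos_total + nrow(t)
      # objectness target at the positive cells: clamped detached CIoU
      pos_in_obj <- (t$a - 1L) * Hg * Wg * N + (t$n - 1) * Hg * Wg +
        t$j * Hg + t$i + 1L
      obj_t[pos_in_obj] <- if (identical(cfg$obj_target, "one")) 1
                           else pmax(0, pmin(1, ciou$v))
      if (n_classes > 1L) {
        for (k in seq_len(n_classes)) {
          tk <- as.numeric(t$cls == (k - 1L))
          lc <- op_bce_logits(op_gather(o, cell_flat(base + 5L + k)), tk)
          total <- add_term(total, op_affine(lc, cfg$cls_gain / nrow(t)))
        }
      }
    }
    obj_pred <- op_gather(o, obj_idx)
    lobj <- op_affine(op_bce_logits(obj_pred, obj_t),
                      cfg$obj_gain * balance[s] / length(obj_idx))
    total <- add_term(total, lobj)
  }
  if (!is.null(box_sum) && n_pos_total > 0)
    total <- add_term(total,
                      op_affine(box_sum, cfg$box_gain / n_pos_total))
  op_affine(total, N)   # scale by batch size, v5 convention
}

# ---- optimizer ----------------------------------------------------------

sgd_init <- function(params) lapply(params, function(p) NULL)

sgd_step <- function(params, state, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$g)) next
    g <- p$g
    if (weight_decay > 0 && is.matrix(p$v)) g <- g + weight_decay * p$v
    buf <- state[[nm]]
    buf <- if (is.null(buf)) g else momentum * buf + g
    state[[nm]] <- buf
    p$v <- p$v - lr * buf
  }
  state
}

cosine_lr <- function(epoch, cfg) {
  if (cfg$warmup_epochs > 0 && epoch <= cfg$warmup_epochs)
    return(cfg$lr0 * epoch / cfg$warmup_epochs)
  t <- (epoch - 1) / max(1, cfg$epochs - 1)
  cfg$lr0 * (cfg$lrf + 0.5 * (1 - cfg$lrf) * (1 + cos(pi * t)))
}

# ---- augmentation -------------------------------------------------------

downscale2 <- function(img) {
  d <- dim(img)
  (img[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   img[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   img[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
   img[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
}

mosaic4 <- function(samples) {
  d <- dim(samples[[1]]$image)
  H <- d[1]; W <- d[2]
  canvas <- array(1, c(2 * H, 2 * W, 3))
  boxes <- list()
  offs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (q in 1:4) {
    s <- samples[[q]]
    oy <- offs[[q]][1]; ox <- offs[[q]][2]
    canvas[oy * H + seq_len(H), ox * W + seq_len(W), ] <- s$image
    b <- s$boxes
    if (nrow(b)) {
      b[, "cx"] <- (b[, "cx"] + ox) / 2
      b[, "cy"] <- (b[, "cy"] + oy) / 2
      b[, "w"] <- b[, "w"] / 2
      b[, "h"] <- b[, "h"] / 2
      boxes[[length(boxes) + 1L]] <- b
    }
  }
  list(image = downscale2(canvas),
       boxes = if (length(boxes)) do.call(rbind, boxes)
               else samples[[1]]$boxes[0, , drop = FALSE])
}

mixup2 <- function(a, b, alpha) {
  lam <- stats::rbeta(1, alpha, alpha)
  list(image = lam * a$image + (1 - lam) * b$image,
       boxes = rbind(a$boxes, b$boxes))
}

# ---- dataset helpers ----------------------------------------------------

#' Render screens into training samples
#'
#' @param screens list of `eeg_screen`s
#' @param input_size square image size, divisible by 32
#' @param render_cfg base [render_config()] (width/height are overridden)
#' @return list of samples: `list(image, boxes)`
#' @export
build_detection_dataset <- function(screens, input_size = 640L,
                                    render_cfg = render_config()) {
  render_cfg$width <- as.integer(input_size)
  render_cfg$height <- as.integer(input_size)
  lapply(screens, function(scr)
    list(image = render_screen(scr, render_cfg),
         boxes = boxes_for_bad_trials(scr),
         screen = scr))
}

samples_to_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(3L, d[1], d[2], length(samples)))
  for (i in seq_along(samples))
    x[, , , i] <- aperm(samples[[i]]$image, c(3, 1, 2))
  x
}

#' Evaluate a model on samples
#'
#' Detections are collected at a near-zero confidence (`det_conf`) so the
#' AP sweep sees the full ranking; precision/recall/F1 are reported at the
#' `conf_thresh` operating point.
#'
#' @param model built detector
#' @param samples list from [build_detection_dataset()]
#' @param conf_thresh operating confidence for P/R/F1
#' @param iou_thresh NMS IoU threshold
#' @param det_conf collection threshold feeding the AP sweep
#' @return list from [evaluate_detections()] plus `det_list`
#' @export
eval_model <- function(model, samples, conf_thresh = 0.25,
                       iou_thresh = 0.45, det_conf = 0.01) {
  det_list <- lapply(samples, function(s)
    detect(model, s$image, det_conf, iou_thresh))
  truth_list <- lapply(samples, function(s) s$boxes)
  res <- evaluate_detections(det_list, truth_list, iou_thresh = 0.5,
                             conf_thresh = conf_thresh)
  res$det_list <- det_list
  res
}

# ---- training loop ------------------------------------------------------

#' Train a detector
#'
#' SGD with momentum and weight decay, cosine-annealed learning rate with
#' linear warmup, optional mosaic/mixup augmentation, per-epoch validation
#' mAP@0.5, early stopping after `patience` stagnant epochs, and return of
#' the best-validation-mAP weights.
#'
#' @param model a built detector (modified in place; also returned)
#' @param train_samples,val_samples sample lists from
#'   [build_detection_dataset()]
#' @param cfg a [train_config()]
#' @param verbose print a line per epoch?
#' @return list with `model` (best weights restored) and `history`
#'   data.frame (epoch, lr, loss, val precision/recall/mAP/F1)
#' @export
train_model <- function(model, train_samples, val_samples,
                        cfg = train_config(), verbose = FALSE) {
  if (!length(train_samples)) stop("empty training set")
  set.seed(cfg$seed)
  if (cfg$auto_anchors) {
    wh <- do.call(rbind, lapply(train_samples, function(s)
      s$boxes[, c("w", "h"), drop = FALSE]))
    if (!is.null(wh) && nrow(wh) >= 1)
      model$cfg$anchors <- kmeans_anchors(wh * model$cfg$input_size)
  }
  params <- module_params(model)
  state <- sgd_init(params)
  history <- list()
  best_map <- -Inf
  best_state <- NULL
  stagnant <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch, cfg)
    ord <- sample(length(train_samples))
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      batch <- lapply(idx, function(i) {
        s <- train_samples[[i]]
        if (cfg$mosaic && stats::runif(1) < 0.5) {
          others <- sample(length(train_samples), 3, replace = TRUE)
          s <- mosaic4(c(list(s), train_samples[others]))
        }
        if (cfg$mixup_alpha > 0 && stats::runif(1) < 0.1) {
          other <- train_samples[[sample(length(train_samples), 1)]]
          s <- mixup2(s, other, cfg$mixup_alpha)
        }
        s
      })
      x <- samples_to_batch(batch)
      boxes_list <- lapply(batch, `[[`, "boxes")
      loss <- yb_with_grad({
        outs <- model$forward(yb_tensor(x), training = TRUE)
        compute_loss(outs, boxes_list, cfg, model$cfg$anchors,
                     model$cfg$input_size, model$cfg$n_classes)
      })
      if (!is.finite(loss$v)) stop("non-finite training loss")
      yb_zero_grad(params)
      yb_backward(loss)
      state <- sgd_step(params, state, lr, cfg$momentum, cfg$weight_decay)
      epoch_loss <- epoch_loss + loss$v
      nb <- nb + 1L
    }
    ev <- if (length(val_samples))
      eval_model(model, val_samples, cfg$conf_thresh, cfg$iou_thresh)
    else list(precision = NA, recall = NA, map = NA, f1 = NA)
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, loss = epoch_loss / max(1L, nb),
      val_precision = ev$precision, val_recall = ev$recall,
      val_map = ev$map, val_f1 = ev$f1)
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.5f loss %8.4f val mAP %.3f", epoch, lr,
        epoch_loss / max(1L, nb), ev$map))
    if (length(val_samples)) {
      if (is.finite(ev$map) && ev$map > best_map + 1e-9) {
        best_map <- ev$map
        best_state <- snapshot_state(model)
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= cfg$patience) break
      }
    }
  }
  if (!is.null(best_state)) restore_state(model, best_state)
  list(model = model, history = do.call(rbind, history),
       best_val_map = if (is.finite(best_map)) best_map else NA_real_)
}
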