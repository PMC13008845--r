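# Detector assembly, decoding, NMS, checkpoints and profiling mechanics.

small_cfg <- function(...) {
  detector_config(width_multiple = 0.125, input_size = 64L, ...)
}

test_that("head grids follow the stride arithmetic", {
  set.seed(60)
  model <- build_model(small_cfg())
  x <- array(runif(3 * 64 * 64), c(3, 64, 64, 1))
  outs <- yolobt:::yb_no_grad(model$forward(yolobt:::yb_tensor(x)))
  expect_equal(dim(outs[[1]]$v)[2:3], c(8L, 8L))
  expect_equal(dim(outs[[2]]$v)[2:3], c(4L, 4L))
  expect_equal(dim(outs[[3]]$v)[2:3], c(2L, 2L))
  expect_equal(dim(outs[[1]]$v)[1], 3L * (1L + 5L))
  expect_error(detector_config(input_size = 100), "divisible by 32")
})

test_that("toggles reduce to the baseline graph and builds are deterministic", {
  set.seed(61)
  base <- build_model(small_cfg(clab = FALSE, hfgm = FALSE, gicm = FALSE))
  set.seed(61)
  base2 <- build_model(small_cfg(clab = FALSE, hfgm = FALSE, gicm = FALSE))
  expect_identical(yolobt:::n_params(base), yolobt:::n_params(base2))
  expect_identical(module_params(base)$stem.conv.w$v,
                   module_params(base2)$stem.conv.w$v)
  # baseline has no attention modules anywhere in its tree
  nms_of <- function(m) {
    out <- character(0)
    walk <- function(mm) {
      out <<- c(out, mm$type)
      for (ch in mm$children) walk(ch)
    }
    walk(m)
    out
  }
  types <- nms_of(base)
  expect_false(any(c("gicm", "hfgm", "clab_bottleneck", "cbam_ca") %in%
                     types))
  full <- build_model(small_cfg())
  expect_true(all(c("gicm", "hfgm", "clab_bottleneck") %in% nms_of(full)))
  expect_gt(yolobt:::n_params(full), yolobt:::n_params(base))
})

test_that("box decoding matches a hand computation on a one-cell head", {
  # single anchor, single cell: raw (x,y,w,h,obj,cls)
  raw <- array(0, c(6, 1, 1, 1))
  raw[, 1, 1, 1] <- c(0.2, -0.3, 0.1, 0.4, 1.5, 0.8)
  anchors <- matrix(c(20, 60), 1)
  d <- yolobt:::decode_head(raw, anchors, input_size = 64L, n_classes = 1L)
  s <- function(z) 1 / (1 + exp(-z))
  expect_equal(d$cx, (2 * s(0.2) - 0.5 + 0) / 1)
  expect_equal(d$cy, (2 * s(-0.3) - 0.5 + 0) / 1)
  expect_equal(d$w, (2 * s(0.1))^2 * 20 / 64)
  expect_equal(d$h, (2 * s(0.4))^2 * 60 / 64)
  expect_equal(d$conf, s(1.5) * s(0.8))
})

test_that("NMS keeps the highest-confidence of overlapping boxes", {
  dets <- data.frame(cx = c(0.5, 0.5, 0.2), cy = 0.5, w = 0.1, h = 1,
                     conf = c(0.8, 0.9, 0.7))
  out <- nms(dets, iou_thresh = 0.45)
  expect_equal(nrow(out), 2L)
  expect_equal(out$conf, c(0.9, 0.7))
  # untouched when boxes are disjoint
  dets2 <- data.frame(cx = c(0.1, 0.5, 0.9), cy = 0.5, w = 0.1, h = 1,
                      conf = c(0.6, 0.5, 0.4))
  expect_equal(nrow(nms(dets2)), 3L)
})

test_that("an untrained model with the negative objectness prior detects nothing", {
  set.seed(62)
  model <- build_model(small_cfg(clab = FALSE, hfgm = FALSE, gicm = FALSE))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(nrow(detect(model, img, conf_thresh = 0.25)), 0L)
  expect_error(detect(model, array(0, c(32, 32, 3))), "must be 64 x 64")
})

test_that("checkpoints round-trip detections exactly", {
  set.seed(63)
  model <- build_model(small_cfg())
  # perturb a head bias so some detections exist
  model$children$head_p3$params$b$v[5] <- 2
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  d1 <- detect(model, img, conf_thresh = 0.05)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  d2 <- detect(back, img, conf_thresh = 0.05)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("loss is finite on a first batch for all four ablation configs", {
  set.seed(64)
  x <- array(runif(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  boxes <- list(box_row(0.25), box_row(0.65))
  tc <- train_config(batch_size = 2, mosaic = FALSE, mixup_alpha = 0,
                     auto_anchors = FALSE, seed = 1)
  for (cfg in ablation_configs(width_multiple = 0.125, input_size = 64L)) {
    model <- build_model(cfg)
    loss <- yolobt:::yb_with_grad({
      outs <- model$forward(yolobt:::yb_tensor(x), training = TRUE)
      yolobt:::compute_loss(outs, boxes, tc, cfg$anchors, cfg$input_size,
                            cfg$n_classes)
    })
    expect_true(is.finite(loss$v))
  }
})

test_that("profiling is deterministic and counts exactly", {
  cfg <- small_cfg()
  p1 <- profile_model(cfg, classes = 80L, input_size = 64L)
  p2 <- profile_model(cfg, classes = 80L, input_size = 64L)
  expect_identical(p1$params, p2$params)
  expect_identical(p1$macs, p2$macs)
  # conv MAC counting on a known tiny case: one 3x3 conv, 4->8 channels,
  # 16x16 input = 4*9*8*16*16 MACs + bn/act elementwise
  m <- yolobt:::cba_layer(4L, 8L, 3L)
  x <- yolobt:::yb_tensor(array(0, c(4, 16, 16, 1)))
  yb <- yolobt:::.yb
  yb$macs <- 0
  yb$count_macs <- TRUE
  invisible(yolobt:::yb_no_grad(m$forward(x)))
  yb$count_macs <- FALSE
  expect_equal(yb$macs, 4 * 9 * 8 * 256 + 2 * 8 * 256)
})

test_that("kmeans anchors handle degenerate identical boxes", {
  set.seed(65)
  wh <- matrix(rep(c(16, 160), 30), ncol = 2, byrow = TRUE)
  a <- kmeans_anchors(wh)
  expect_length(a, 3L)
  expect_true(all(vapply(a, nrow, 0L) == 3L))
  areas <- unlist(lapply(a, function(m) m[, 1] * m[, 2]))
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("yaml subset round-trips the structures the package writes", {
  f <- withr::local_tempfile(fileext = ".yaml")
  x <- list(version = 1L, n = 3, train = c("a", "b"), val = "c",
            flag = TRUE, rate = 0.25)
  yaml_write(x, f)
  back <- yaml_read(f)
  expect_equal(back$n, 3)
  expect_equal(back$train, c("a", "b"))
  expect_equal(back$flag, TRUE)
  expect_equal(back$rate, 0.25)
})
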