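# Detector assembly and architecture profiling.
#
# The network is the small-variant CSP one-stage detector: a stem plus four
# downsampling stages with C3 blocks (CLAC3 when the `clab` toggle is on),
# an SPPF, a top-down fusion path whose upsample+concat nodes are replaced
# by HFGM when `hfgm` is on, a bottom-up path with strided convolutions,
# GICM instances before each of the three heads when `gicm` is on, and
# 1x1 prediction convolutions at strides 8/16/32.

make_divisible <- function(x, divisor = 8L) {
  as.integer(max(divisor, round(x / divisor) * divisor))
}

#' Default anchor set (pixels at 640, three per scale)
#' @return list of 3x2 matrices (w,h) for strides 8/16/32
#' @export
default_anchors <- function() {
  list(p3 = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
       p4 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
       p5 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
}

#' Detector configuration
#'
#' @param depth_multiple,width_multiple small-variant scaling factors
#' @param n_classes number of detection classes (1: "bad")
#' @param input_size square input resolution in pixels, divisible by 32
#' @param clab,hfgm,gicm module toggles for ablation
#' @param anchors anchor list as in [default_anchors()], pixel units at
#'   `input_size`
#' @param gicm_branch_width local-branch width of each GICM convolution
#' @param gicm_dk_ratio key/query width as a fraction of the scale channels
#' @param token_pool maximum GICM attention tokens
#' @return a `detector_config` object
#' @export
detector_config <- function(depth_multiple = 0.33, width_multiple = 0.50,
                            n_classes = 1L, input_size = 640L,
                            clab = TRUE, hfgm = TRUE, gicm = TRUE,
                            anchors = default_anchors(),
                            gicm_branch_width = 17L, gicm_dk_ratio = 0.5,
                            token_pool = 3136L) {
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  if (n_classes < 1L) stop("n_classes must be >= 1")
  structure(list(depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 clab = isTRUE(clab), hfgm = isTRUE(hfgm),
                 gicm = isTRUE(gicm), anchors = anchors,
                 gicm_branch_width = as.integer(gicm_branch_width),
                 gicm_dk_ratio = gicm_dk_ratio,
                 token_pool = as.integer(token_pool)),
            class = "detector_config")
}

#' The four ablation configurations
#'
#' Experiment 1: plain baseline; 2: + CLAB; 3: + CLAB + HFGM;
#' 4: the full model (+ GICM).
#'
#' @param ... arguments forwarded to [detector_config()]
#' @return named list of four [detector_config()]s
#' @export
ablation_configs <- function(...) {
  list(
    baseline = detector_config(clab = FALSE, hfgm = FALSE, gicm = FALSE,
                               ...),
    clab = detector_config(clab = TRUE, hfgm = FALSE, gicm = FALSE, ...),
    clab_hfgm = detector_config(clab = TRUE, hfgm = TRUE, gicm = FALSE,
                                ...),
    full = detector_config(clab = TRUE, hfgm = TRUE, gicm = TRUE, ...))
}

#' Build the detector
#'
#' Parameters are drawn from the current R RNG; call `set.seed()` first for
#' a reproducible build.
#'
#' @param cfg a [detector_config()]
#' @return a model object (environment) with `$forward`, `$cfg`, `$strides`
#' @export
build_model <- function(cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  gd <- cfg$depth_multiple
  gw <- cfg$width_multiple
  ch <- function(x) make_divisible(x * gw)
  dn <- function(n) max(1L, as.integer(round(n * gd)))
  nc <- cfg$n_classes
  na <- nrow(cfg$anchors[[1]])
  no <- na * (nc + 5L)

  m <- new_module("detector")
  m$cfg <- cfg
  m$strides <- c(8L, 16L, 32L)
  c1 <- ch(64); c2 <- ch(128); c3 <- ch(256); c4 <- ch(512); c5 <- ch(1024)

  m$children$stem <- cba_layer(3L, c1, 6L, 2L, 2L)
  m$children$down1 <- cba_layer(c1, c2, 3L, 2L)
  m$children$stage1 <- c3_layer(c2, c2, dn(3), TRUE, cfg$clab)
  m$children$down2 <- cba_layer(c2, c3, 3L, 2L)
  m$children$stage2 <- c3_layer(c3, c3, dn(6), TRUE, cfg$clab)
  m$children$down3 <- cba_layer(c3, c4, 3L, 2L)
  m$children$stage3 <- c3_layer(c4, c4, dn(9), TRUE, cfg$clab)
  m$children$down4 <- cba_layer(c4, c5, 3L, 2L)
  m$children$stage4 <- c3_layer(c5, c5, dn(3), TRUE, cfg$clab)
  m$children$sppf <- sppf_layer(c5, c5)

  m$children$red1 <- cba_layer(c5, c4, 1L)
  if (cfg$hfgm) m$children$hfgm1 <- hfgm_layer(c4, c4, 2L)
  m$children$hc3_1 <- c3_layer(2L * c4, c4, dn(3), FALSE)
  m$children$red2 <- cba_layer(c4, c3, 1L)
  if (cfg$hfgm) m$children$hfgm2 <- hfgm_layer(c3, c3, 2L)
  m$children$hc3_2 <- c3_layer(2L * c3, c3, dn(3), FALSE)
  m$children$pan1 <- cba_layer(c3, c3, 3L, 2L)
  m$children$hc3_3 <- c3_layer(2L * c3, c4, dn(3), FALSE)
  m$children$pan2 <- cba_layer(c4, c4, 3L, 2L)
  m$children$hc3_4 <- c3_layer(2L * c4, c5, dn(3), FALSE)

  if (cfg$gicm) {
    dk <- function(c) max(1L, as.integer(round(c * cfg$gicm_dk_ratio)))
    m$children$gicm_p3 <- gicm_layer(c3, dk(c3), cfg$gicm_branch_width,
                                     cfg$token_pool)
    m$children$gicm_p4 <- gicm_layer(c4, dk(c4), cfg$gicm_branch_width,
                                     cfg$token_pool)
    m$children$gicm_p5 <- gicm_layer(c5, dk(c5), cfg$gicm_branch_width,
                                     cfg$token_pool)
  }

  m$children$head_p3 <- conv_layer(c3, no, 1L, bias = TRUE)
  m$children$head_p4 <- conv_layer(c4, no, 1L, bias = TRUE)
  m$children$head_p5 <- conv_layer(c5, no, 1L, bias = TRUE)
  # bias prior: start objectness near zero probability so the untrained
  # model emits no detections
  for (nm in c("head_p3", "head_p4", "head_p5")) {
    b <- m$children[[nm]]$params$b$v
    obj_idx <- (seq_len(na) - 1L) * (nc + 5L) + 5L
    b[obj_idx] <- -5
    m$children[[nm]]$params$b$v <- b
  }

  m$forward <- function(x, training = FALSE) {
    ch_m <- m$children
    x <- as_feature_map(x)
    x <- ch_m$stem$forward(x, training)
    x <- ch_m$down1$forward(x, training)
    x <- ch_m$stage1$forward(x, training)
    x <- ch_m$down2$forward(x, training)
    p3 <- ch_m$stage2$forward(x, training)
    x <- ch_m$down3$forward(p3, training)
    p4 <- ch_m$stage3$forward(x, training)
    x <- ch_m$down4$forward(p4, training)
    x <- ch_m$stage4$forward(x, training)
    p5 <- ch_m$sppf$forward(x, training)

    t10 <- ch_m$red1$forward(p5, training)
    f1 <- if (cfg$hfgm) ch_m$hfgm1$forward2(p4, t10, training)
          else op_concat(list(op_upsample2(t10), p4))
    x13 <- ch_m$hc3_1$forward(f1, training)
    t14 <- ch_m$red2$forward(x13, training)
    f2 <- if (cfg$hfgm) ch_m$hfgm2$forward2(p3, t14, training)
          else op_concat(list(op_upsample2(t14), p3))
    x17 <- ch_m$hc3_2$forward(f2, training)
    x18 <- ch_m$pan1$forward(x17, training)
    x20 <- ch_m$hc3_3$forward(op_concat(list(x18, t14)), training)
    x21 <- ch_m$pan2$forward(x20, training)
    x23 <- ch_m$hc3_4$forward(op_concat(list(x21, t10)), training)

    if (cfg$gicm) {
      x17 <- ch_m$gicm_p3$forward(x17, training)
      x20 <- ch_m$gicm_p4$forward(x20, training)
      x23 <- ch_m$gicm_p5$forward(x23, training)
    }
    list(ch_m$head_p3$forward(x17, training),
         ch_m$head_p4$forward(x20, training),
         ch_m$head_p5$forward(x23, training))
  }
  m
}

#' Profile a detector configuration
#'
#' Builds the model and measures the trainable parameter count and the
#' forward-pass compute of one `input_size` x `input_size` image.  GFLOPs
#' are reported as twice the multiply-accumulate count: convolutions and
#' matrix products count exactly, and every batch-norm, activation or other
#' elementwise arithmetic result element counts as one MAC.  By convention
#' profiling uses 80-class prediction heads for comparability with
#' published detector tables; the deployed bad-trial model itself uses a
#' single class.
#'
#' @param cfg a [detector_config()]
#' @param classes head class count used for profiling (default 80)
#' @param input_size override the profiled resolution
#' @return list with `params` (count), `params_m` (millions, 1 decimal),
#'   `macs`, `gflops` (1 decimal)
#' @export
profile_model <- function(cfg = detector_config(), classes = 80L,
                          input_size = cfg$input_size) {
  pcfg <- cfg
  pcfg$n_classes <- as.integer(classes)
  pcfg$input_size <- as.integer(input_size)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(0L)
  model <- build_model(pcfg)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  params <- n_params(model)
  x <- array(0, c(3L, pcfg$input_size, pcfg$input_size, 1L))
  .yb$macs <- 0
  .yb$count_macs <- TRUE
  on.exit(.yb$count_macs <- FALSE)
  invisible(yb_no_grad(model$forward(yb_tensor(x))))
  .yb$count_macs <- FALSE
  macs <- .yb$macs
  list(params = params,
       params_m = round(params / 1e6, 1),
       macs = macs,
       gflops = round(2 * macs / 1e9, 1))
}
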