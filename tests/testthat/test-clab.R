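# Cross-layer attention bottleneck: SE, CBAM channel/spatial attention,
# CLAM fusion and the assembled CLAC3 stage, against scalar oracles.

test_that("se_recalibrate matches the scalar oracle and preserves shape", {
  set.seed(10)
  se <- new_se(2, reduction = 1)  # hidden = 2: both MLP layers exercised
  x <- rt(2, 2, 2)
  ref <- se_oracle(x, se$params$w1$v, se$params$w2$v)
  out <- se_recalibrate(x, se)
  expect_equal(out, ref$out, tolerance = 1e-10)
  expect_equal(dim(out), dim(x))
  # channel-symmetric weights + constant input -> equal gates -> uniform
  # scaling (the shared MLP treats all channels alike)
  se4 <- new_se(4, reduction = 2)
  se4$params$w1$v <- matrix(0.3, 2, 4)
  se4$params$w2$v <- matrix(-0.2, 4, 2)
  xc <- array(3, c(4, 3, 3))
  outc <- se_recalibrate(xc, se4)
  expect_equal(length(unique(round(as.numeric(outc / xc), 12))), 1L)
})

test_that("channel attention follows sigma(MLP(avg) + MLP(max))", {
  set.seed(11)
  ca <- new_channel_attention(3, reduction = 1)
  x <- rt(3, 4, 4)
  r <- channel_attention(x, ca)
  # scalar oracle
  avg <- vapply(1:3, function(c) mean(x[c, , ]), 0)
  mx <- vapply(1:3, function(c) max(x[c, , ]), 0)
  mlp <- function(z) ca$params$w2$v %*% pmax(ca$params$w1$v %*% z, 0)
  mc <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  expect_equal(r$weights, as.numeric(mc), tolerance = 1e-10)
  expect_true(all(r$weights > 0 & r$weights < 1))
  expect_equal(r$output, x * as.numeric(mc), tolerance = 1e-10)
  # degenerate pooling: H = W = 1 makes avg = max, so Mc = sigma(2 MLP(x))
  x1 <- rt(3, 1, 1)
  r1 <- channel_attention(x1, ca)
  z <- as.numeric(x1)
  expect_equal(r1$weights, as.numeric(1 / (1 + exp(-2 * mlp(z)))),
               tolerance = 1e-10)
})

test_that("spatial attention matches a direct 2-D convolution oracle", {
  set.seed(12)
  sa <- new_spatial_attention(7)
  x <- rt(1, 8, 8)
  s <- spatial_attention(x, sa)
  expect_equal(dim(s), c(1, 8, 8))
  expect_true(all(s > 0 & s < 1))
  stacked <- array(0, c(2, 8, 8))
  stacked[1, , ] <- x[1, , ]   # channel mean of a 1-channel map
  stacked[2, , ] <- x[1, , ]   # channel max likewise
  ref <- conv2d_oracle(stacked, sa$children$conv$params$w$v,
                       sa$children$conv$params$b$v, k = 7, pad = 3)
  expect_equal(s, 1 / (1 + exp(-ref)), tolerance = 1e-10)
  # channel-constant input: the two pooled maps coincide
  xc <- array(rep(rnorm(16), each = 3), c(3, 4, 4))
  st <- yolobt:::op_concat(list(
    yolobt:::op_chan_mean(yolobt:::as_feature_map(xc)),
    yolobt:::op_chan_max(yolobt:::as_feature_map(xc))))
  expect_equal(st$v[1, , , 1], st$v[2, , , 1], tolerance = 1e-12)
})

test_that("clam_fuse composes SE and 1x1 fusion as written", {
  set.seed(13)
  clam <- new_clam(2, reduction = 1)
  s1 <- array(runif(16), c(1, 4, 4))
  s2 <- array(runif(16), c(1, 4, 4))
  out <- clam_fuse(list(s1), s2, clam)
  expect_equal(dim(out), c(1, 4, 4))
  # scalar composition oracle of concat -> SE -> 1x1
  stacked <- array(0, c(2, 4, 4))
  stacked[1, , ] <- s1; stacked[2, , ] <- s2
  se_part <- se_oracle(stacked, clam$children$se$params$w1$v,
                       clam$children$se$params$w2$v)$out
  w <- clam$children$fuse$params$w$v
  ref <- w[1, 1] * se_part[1, , ] + w[1, 2] * se_part[2, , ] +
    clam$children$fuse$params$b$v
  expect_equal(out[1, , ], ref, tolerance = 1e-10)
  # single-map fusion keeps shape
  clam1 <- new_clam(1)
  expect_equal(dim(clam_fuse(list(), s1, clam1)), c(1, 4, 4))
  # two identical inputs are order-symmetric
  clam2 <- new_clam(2)
  a <- clam_fuse(list(s1), s1, clam2)
  expect_equal(a, clam_fuse(list(s1), s1, clam2), tolerance = 1e-12)
})

test_that("clab_forward composes the verified primitives and extends history", {
  set.seed(14)
  clab <- new_clab(4, layer_index = 1, shortcut = FALSE)
  x <- rt(4, 5, 5)
  r <- clab_forward(x, list(), clab)
  expect_equal(dim(r$output), dim(x))
  expect_length(r$history, 1L)
  # composition oracle from the exported primitives
  b_n <- yolobt:::fm_value(yolobt:::yb_no_grad(
    clab$children$cv2$forward(clab$children$cv1$forward(
      yolobt:::as_feature_map(x)))))
  b_p <- channel_attention(b_n, clab$children$ca)$output
  s_n <- spatial_attention(b_p, clab$children$sa)
  fs <- clam_fuse(list(), s_n, clab$children$clam)
  gated <- b_n * as.numeric(rep(fs[1, , ], each = 4))
  ref <- se_recalibrate(gated, clab$children$se_out)
  expect_equal(r$output, ref, tolerance = 1e-8)
  expect_equal(r$history[[1]], s_n, tolerance = 1e-12)
})

test_that("clac3 threads a stage-local history and keeps dimensions", {
  set.seed(15)
  stage <- new_clac3(8, 8, n = 3)
  x <- rt(8, 6, 6)
  out <- clac3_forward(x, stage)
  expect_equal(dim(out), c(8, 6, 6))
  # bottleneck k consumes a history of exactly k-1 maps: CLAM of bottleneck
  # k is sized for k channels
  for (k in 1:3)
    expect_equal(ncol(stage$children[[paste0("m", k)]]$children$clam$
                        children$fuse$params$w$v), k)
  # gates strictly inside (0,1), activations finite
  expect_true(all(is.finite(out)))
})

test_that("attention gates stay in (0,1) and maps stay finite on random input", {
  set.seed(16)
  for (i in 1:5) {
    x <- rt(4, 5, 5, sd = 2)
    sa <- new_spatial_attention()
    s <- spatial_attention(x, sa)
    expect_true(all(s > 0 & s < 1))
    ca <- new_channel_attention(4)
    w <- channel_attention(x, ca)$weights
    expect_true(all(w > 0 & w < 1))
  }
})
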