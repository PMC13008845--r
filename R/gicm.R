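# Global Information Classification Module (GICM).
#
# An inception-style local branch (five parallel convolutions with kernels
# 1,3,5,7,9, channel attention, 1x1 reduction, sigmoid) produces a spatial
# gate L in (0,1) that modulates the Value of a single-head global
# self-attention branch:
#
#   L        = Local(X)                               # 1 x H x W gate
#   X_global = SpatialAttention(X)                    # CBAM-style gate
#   K, Q     = conv1x1(X_global)                      # d_k channels
#   V        = L (x) conv1x1(X_global)                # C channels
#   X_out    = softmax(Q K' / sqrt(d_k)) V            # token attention
#
# When H*W exceeds `token_pool`, the K/Q/V maps are adaptively
# average-pooled to at most that many tokens before attention and the
# output is nearest-upsampled back; attention is exact on small grids.
# The attention branch enters through a residual connection, modulating
# the feature map feeding the detection head.

gicm_layer <- function(c, d_k = NULL, branch_width = 16L, token_pool = 400L,
                       reduction = 16L) {
  m <- new_module("gicm")
  if (is.null(d_k)) d_k <- max(1L, c %/% 2L)
  m$c <- as.integer(c)
  m$d_k <- as.integer(d_k)
  m$token_pool <- as.integer(token_pool)
  kernels <- c(1L, 3L, 5L, 7L, 9L)
  for (i in seq_along(kernels))
    m$children[[paste0("br", kernels[i])]] <-
      conv_layer(c, branch_width, kernels[i], bias = TRUE)
  m$children$ca <- se_layer(5L * branch_width, reduction)
  m$children$reduce <- conv_layer(5L * branch_width, 1L, 1L, bias = TRUE)
  m$children$sa <- spatial_attn_layer(7L)
  m$children$k <- conv_layer(c, m$d_k, 1L, bias = TRUE)
  m$children$q <- conv_layer(c, m$d_k, 1L, bias = TRUE)
  m$children$v <- conv_layer(c, c, 1L, bias = TRUE)
  # zero-init the Value projection: the residual branch starts as the
  # identity and the attention correction grows in during training
  m$children$v$params$w$v[] <- 0
  m$children$v$params$b$v[] <- 0
  m$kernels <- kernels

  m$local <- function(x, training = FALSE) {
    brs <- lapply(m$kernels, function(k) m$children[[paste0("br", k)]])
    merged <- op_conv2d_multi(x,
                              lapply(brs, function(b) b$params$w),
                              lapply(brs, function(b) b$params$b),
                              m$kernels)
    merged <- m$children$ca$forward(merged, training)
    op_sigmoid(m$children$reduce$forward(merged, training))
  }

  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    H <- d[2]; W <- d[3]
    l_feat <- m$local(x, training)
    x_glob <- m$children$sa$forward(x, training)
    km <- m$children$k$forward(x_glob, training)
    qm <- m$children$q$forward(x_glob, training)
    vm <- op_smul(m$children$v$forward(x_glob, training), l_feat)
    if (H * W > m$token_pool) {
      side <- max(1L, as.integer(floor(sqrt(m$token_pool))))
      th <- min(H, side); tw <- min(W, side)
      km <- op_adaptive_avgpool(km, th, tw)
      qm <- op_adaptive_avgpool(qm, th, tw)
      vm <- op_adaptive_avgpool(vm, th, tw)
    } else {
      th <- H; tw <- W
    }
    K <- op_tokens(km); Q <- op_tokens(qm); V <- op_tokens(vm)
    att <- op_softmax_rows(op_affine(op_bmm(Q, K, transpose_b = TRUE),
                                     a = 1 / sqrt(m$d_k)))
    out <- op_untokens(op_bmm(att, V), th, tw)
    if (th != H || tw != W) out <- op_upsample_to(out, H, W)
    # residual: the attention branch modulates the head input rather than
    # replacing it (a pure replacement is untrainable at small scale --
    # the head would see only softmax-mixed tokens from the start)
    op_add(x, out)
  }
  m
}

# nearest-neighbour upsampling to an arbitrary (H,W) target
op_upsample_to <- function(x, H, W) {
  d <- dim(x$v)
  ih <- floor((seq_len(H) - 1) * d[2] / H) + 1
  iw <- floor((seq_len(W) - 1) * d[3] / W) + 1
  out <- x$v[, ih, iw, , drop = FALSE]
  yb_op(out, list(x), function(g) {
    dx <- array(0, d)
    for (h in seq_len(H))
      for (w in seq_len(W))
        dx[, ih[h], iw[w], ] <- dx[, ih[h], iw[w], ] + g[, h, w, ]
    list(dx)
  })
}

# ---- functional wrappers ------------------------------------------------

#' Create a global information classification module
#'
#' @param channels input channel count `C`
#' @param d_k key/query projection width (default `C / 2`)
#' @param branch_width output channels of each local-branch convolution
#' @param token_pool maximum number of attention tokens before pooling
#' @param reduction channel-attention reduction ratio
#' @return a GICM module
#' @export
new_gicm <- function(channels, d_k = NULL, branch_width = 16L,
                     token_pool = 400L, reduction = 16L) {
  if (token_pool < 1L) stop("token_pool must be at least 1")
  gicm_layer(channels, d_k, branch_width, token_pool, reduction)
}

#' Local multi-scale gating branch
#'
#' Five parallel convolutions (kernels 1,3,5,7,9, size-preserving padding),
#' channel concatenation, channel-attention reweighting, 1x1 reduction to a
#' single channel and a sigmoid.
#'
#' @param x feature map array `C x H x W`
#' @param gicm module from [new_gicm()]
#' @return single-channel gate array `1 x H x W` in (0,1)
#' @export
local_branch <- function(x, gicm) {
  fm_value(yb_no_grad(gicm$local(as_feature_map(x))))
}

#' Spatially gated input of the global branch
#'
#' Applies the spatial-attention operator (pooled-map 7x7 convolution +
#' sigmoid, map times input) to concentrate the global branch on candidate
#' artifact regions.
#'
#' @inheritParams local_branch
#' @return gated feature map, same shape as `x`
#' @export
global_gate <- function(x, gicm) {
  fm_value(yb_no_grad(gicm$children$sa$forward(as_feature_map(x))))
}

#' Project the gated map to Key / Query / Value token sequences
#'
#' @param x_global gated feature map array `C x H x W`
#' @param l_feature local gate array `1 x H x W`
#' @param gicm module from [new_gicm()]
#' @return list of matrices `K`, `Q` (`T x d_k`) and `V` (`T x C`),
#'   tokens ordered column-major (h fastest)
#' @export
qkv_project <- function(x_global, l_feature, gicm) {
  xg <- as_feature_map(x_global)
  lf <- as_feature_map(l_feature)
  yb_no_grad({
    km <- op_tokens(gicm$children$k$forward(xg))
    qm <- op_tokens(gicm$children$q$forward(xg))
    vm <- op_tokens(op_smul(gicm$children$v$forward(xg), lf))
  })
  drop3 <- function(t) { v <- t$v; dim(v) <- dim(v)[1:2]; v }
  list(K = drop3(km), Q = drop3(qm), V = drop3(vm))
}

#' Scaled dot-product attention mix
#'
#' `X_output = softmax(Q K' / sqrt(d_k)) V`, rows normalized over keys.
#'
#' @param K,Q token matrices `T x d_k`
#' @param V token matrix `T x C`
#' @param d_k key dimensionality used for the `1/sqrt(d_k)` scaling
#' @return matrix `T x C`
#' @export
attention_mix <- function(K, Q, V, d_k = ncol(K)) {
  if (d_k <= 0) stop("d_k must be positive")
  s <- Q %*% t(K) / sqrt(d_k)
  s <- exp(s - apply(s, 1, max))
  (s / rowSums(s)) %*% V
}

#' Full GICM forward pass
#'
#' @param x feature map array `C x H x W`
#' @param gicm module from [new_gicm()]
#' @return output feature map with the shape of `x`
#' @export
gicm_forward <- function(x, gicm) {
  fm_value(yb_no_grad(gicm$forward(as_feature_map(x))))
}
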