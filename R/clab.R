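# Cross-Layer Attention Bottleneck (CLAB).
#
# Each bottleneck inside a CLAC3 stage runs CBAM-style channel then spatial
# attention on its convolutional output B_n, fuses the resulting spatial
# map S_n with the maps of all previous bottlenecks of the same stage
# (CLAM: concatenate, SE-reweight, 1x1-fuse to a single channel), applies
# the fused gate to B_n and smooths the result with an SE block:
#
#   M_c     = sigmoid(MLP(avg(B)) + MLP(max(B)))          (channel gate)
#   S_n     = sigmoid(f7x7([avg_c(B'); max_c(B')]))       (spatial map)
#   Final_S = g1x1(SE(cat(S_1..S_n)))                     (CLAM fusion)
#   B_out   = SE(Final_S (x) B_n)
#
# The fused map carries no terminal sigmoid; the trailing SE restores
# boundedness of the gating. The attention history is stage-local.

# CLAM for a bottleneck at 1-based `layer_index` (fuses `layer_index` maps)
clam_layer <- function(layer_index, reduction = 16L) {
  m <- new_module("clam")
  nmaps <- layer_index
  m$children$se <- se_layer(nmaps, reduction)
  m$children$fuse <- conv_layer(nmaps, 1L, 1L, bias = TRUE)
  # start the fused gate near 1 so bottleneck branches are alive at init
  # (with a zero-mean fuse the gate starts near 0 and the stage is dead)
  m$children$fuse$params$b$v[] <- 1
  m$forward_maps <- function(maps, training = FALSE) {
    stacked <- if (length(maps) == 1L) maps[[1L]] else op_concat(maps)
    m$children$fuse$forward(m$children$se$forward(stacked, training),
                            training)
  }
  m
}

clab_bottleneck_layer <- function(c1, c2, layer_index, shortcut = TRUE,
                                  reduction = 16L) {
  m <- new_module("clab_bottleneck")
  m$children$cv1 <- cba_layer(c1, c2, 1L)
  m$children$cv2 <- cba_layer(c2, c2, 3L)
  m$children$ca <- cbam_channel_layer(c2, reduction)
  m$children$sa <- spatial_attn_layer(7L)
  m$children$clam <- clam_layer(layer_index, reduction)
  m$children$se_out <- se_layer(c2, reduction)
  m$shortcut <- shortcut && c1 == c2
  m$forward_hist <- function(x, history, training = FALSE) {
    b_n <- m$children$cv2$forward(m$children$cv1$forward(x, training),
                                  training)
    b_prime <- m$children$ca$forward(b_n, training)          # Mc (x) B
    s_n <- m$children$sa$map(b_prime, training)              # 1 x H x W
    final_s <- m$children$clam$forward_maps(c(history, list(s_n)), training)
    out <- m$children$se_out$forward(op_smul(b_n, final_s), training)
    if (m$shortcut) out <- op_add(x, out)
    list(out = out, history = c(history, list(s_n)))
  }
  m$forward <- function(x, training = FALSE)
    m$forward_hist(x, list(), training)$out
  m
}

# ---- functional wrappers (plain-array in, plain-array out) --------------

#' Squeeze-and-excitation channel recalibration
#'
#' Applies the SE gate: per-channel global average pooling, a two-layer
#' bottleneck MLP with ReLU, sigmoid gates, and per-channel rescaling of
#' the input.
#'
#' @param x feature map, array `C x H x W` (or `C x H x W x N`)
#' @param se an SE module from [new_se()]
#' @return recalibrated array with the shape of `x`
#' @export
se_recalibrate <- function(x, se) {
  t <- as_feature_map(x)
  fm_value(yb_no_grad(se$forward(t)))
}

#' Create a squeeze-and-excitation block
#' @param channels channel count of the maps it will gate
#' @param reduction bottleneck reduction ratio of the MLP
#' @return an SE module
#' @export
new_se <- function(channels, reduction = 16L) se_layer(channels, reduction)

#' Create a CBAM channel-attention block
#' @inheritParams new_se
#' @return a channel-attention module
#' @export
new_channel_attention <- function(channels, reduction = 16L)
  cbam_channel_layer(channels, reduction)

#' CBAM channel attention
#'
#' `M_c = sigmoid(MLP(avg(B)) + MLP(max(B)))` with the MLP shared between
#' the two pooled descriptors, then `B' = M_c (x) B`.
#'
#' @param x feature map array
#' @param ca module from [new_channel_attention()]
#' @return list with `weights` (per-channel gates in (0,1)) and `output`
#' @export
channel_attention <- function(x, ca) {
  t <- as_feature_map(x)
  yb_no_grad({
    w <- ca$weights(t)
    out <- op_cmul(t, w)
  })
  list(weights = as.numeric(w$v), output = fm_value(out))
}

#' Create a spatial-attention block (7x7 convolution over pooled maps)
#' @param kernel odd kernel size of the convolution
#' @return a spatial-attention module
#' @export
new_spatial_attention <- function(kernel = 7L) spatial_attn_layer(kernel)

#' Spatial attention map
#'
#' Stacks channel-wise average and max maps, convolves with a `k x k`
#' kernel (padding preserves size) and applies a sigmoid.
#'
#' @param x feature map array
#' @param sa module from [new_spatial_attention()]
#' @return single-channel array `1 x H x W` with values in (0,1)
#' @export
spatial_attention <- function(x, sa) {
  t <- as_feature_map(x)
  fm_value(yb_no_grad(sa$map(t)))
}

#' Create a cross-layer attention fusion (CLAM) block
#' @param layer_index 1-based bottleneck index; the block fuses that many maps
#' @param reduction SE reduction ratio
#' @return a CLAM module
#' @export
new_clam <- function(layer_index, reduction = 16L)
  clam_layer(layer_index, reduction)

#' Fuse a history of spatial attention maps (CLAM)
#'
#' Concatenates the historical maps with the current one, SE-reweights the
#' stack and fuses to a single channel with a 1x1 convolution.  No terminal
#' sigmoid is applied, so the output range is unconstrained.
#'
#' @param history list of earlier `1 x H x W` maps (possibly empty)
#' @param s_n current spatial attention map
#' @param clam module from [new_clam()] sized for `length(history) + 1` maps
#' @return fused single-channel array
#' @export
clam_fuse <- function(history, s_n, clam) {
  maps <- c(lapply(history, as_feature_map), list(as_feature_map(s_n)))
  fm_value(yb_no_grad(clam$forward_maps(maps)))
}

#' Create a cross-layer attention bottleneck
#' @param channels input/output channel count
#' @param layer_index 1-based position within its CLAC3 stage
#' @param shortcut add the residual connection?
#' @param reduction SE / CBAM reduction ratio
#' @return a CLAB module
#' @export
new_clab <- function(channels, layer_index, shortcut = TRUE,
                     reduction = 16L)
  clab_bottleneck_layer(channels, channels, layer_index, shortcut, reduction)

#' Forward pass of one cross-layer attention bottleneck
#'
#' @param x input feature map array
#' @param history list of spatial attention maps from earlier bottlenecks
#'   of the same stage
#' @param clab module from [new_clab()]
#' @return list with `output` and the extended `history`
#' @export
clab_forward <- function(x, history, clab) {
  t <- as_feature_map(x)
  hist <- lapply(history, as_feature_map)
  r <- yb_no_grad(clab$forward_hist(t, hist))
  list(output = fm_value(r$out),
       history = lapply(r$history, fm_value))
}

#' Create a CLAC3 stage (C3 with cross-layer attention bottlenecks)
#' @param c1,c2 input/output channels
#' @param n number of bottlenecks
#' @param shortcut residual connections in the bottlenecks?
#' @return a CLAC3 module
#' @export
new_clac3 <- function(c1, c2, n = 1L, shortcut = TRUE)
  c3_layer(c1, c2, n, shortcut, use_clab = TRUE)

#' Forward pass of a CLAC3 stage
#'
#' Threads a stage-local attention history (starting empty) through the
#' stage's bottlenecks while keeping the CSP split/concat topology.
#'
#' @param x input feature map array
#' @param clac3 module from [new_clac3()]
#' @return output feature map array
#' @export
clac3_forward <- function(x, clac3) {
  fm_value(yb_no_grad(clac3$forward(as_feature_map(x))))
}
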