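# Neural-network building blocks.
#
# A module is an environment with `$params` (named list of yb_tensor),
# `$buffers` (running statistics), `$children` (sub-modules) and `$forward`,
# a closure `function(x, training = FALSE)`.  Parameters are initialized
# from the R RNG at construction time, so `set.seed()` before building a
# model makes it fully reproducible.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  class(m) <- c(paste0("yb_", type), "yb_module")
  m
}

mk_param <- function(v) yb_tensor(v, requires_grad = TRUE)

#' Collect all trainable parameters of a module tree
#' @param m a module
#' @return flat named list of parameter tensors
#' @keywords internal
module_params <- function(m) {
  out <- m$params
  if (length(m$children)) {
    for (nm in names(m$children)) {
      ch <- module_params(m$children[[nm]])
      if (length(ch)) names(ch) <- paste0(nm, ".", names(ch))
      out <- c(out, ch)
    }
  }
  out
}

#' Count trainable parameters
#' @param m a module
#' @return total number of scalar parameters
#' @keywords internal
n_params <- function(m) {
  sum(vapply(module_params(m), function(p) length(p$v), 0))
}

# plain convolution (weight stored as (C2, C1*k*k) matrix)
conv_layer <- function(c1, c2, k = 1L, stride = 1L, pad = NULL,
                       bias = TRUE) {
  if (is.null(pad)) pad <- k %/% 2L
  m <- new_module("conv")
  fan_in <- c1 * k * k
  bd <- sqrt(6 / fan_in)
  m$params$w <- mk_param(matrix(stats::runif(c2 * fan_in, -bd, bd), nrow = c2))
  if (bias) m$params$b <- mk_param(numeric(c2))
  m$k <- k; m$stride <- stride; m$pad <- pad
  m$forward <- function(x, training = FALSE)
    op_conv2d(x, m$params$w, m$params$b, k = m$k, stride = m$stride,
              pad = m$pad)
  m
}

batchnorm_layer <- function(c, eps = 1e-3, momentum = 0.1) {
  m <- new_module("bn")
  m$params$gamma <- mk_param(rep(1, c))
  m$params$beta <- mk_param(numeric(c))
  m$buffers <- new.env(parent = emptyenv())
  m$buffers$rm <- numeric(c)
  m$buffers$rv <- rep(1, c)
  m$eps <- eps; m$momentum <- momentum
  m$forward <- function(x, training = FALSE) {
    st <- if (training) new.env(parent = emptyenv()) else NULL
    out <- op_batchnorm(x, m$params$gamma, m$params$beta, m$buffers$rm,
                        m$buffers$rv, training = training, eps = m$eps,
                        stats_out = st)
    if (training) {
      mom <- m$momentum
      m$buffers$rm <- (1 - mom) * m$buffers$rm + mom * st$mean
      m$buffers$rv <- (1 - mom) * m$buffers$rv + mom * st$var
    }
    out
  }
  m
}

# Conv + BN + SiLU, the standard one-stage detector conv block
cba_layer <- function(c1, c2, k = 1L, stride = 1L, pad = NULL) {
  m <- new_module("cba")
  m$children$conv <- conv_layer(c1, c2, k, stride, pad, bias = FALSE)
  m$children$bn <- batchnorm_layer(c2)
  m$forward <- function(x, training = FALSE) {
    op_silu(m$children$bn$forward(m$children$conv$forward(x), training))
  }
  m
}

# squeeze-and-excitation gate (global average pool + 2-layer MLP + sigmoid)
se_layer <- function(c, reduction = 16L) {
  m <- new_module("se")
  hidden <- max(1L, c %/% reduction)
  b1 <- sqrt(6 / c); b2 <- sqrt(6 / hidden)
  m$params$w1 <- mk_param(matrix(stats::runif(hidden * c, -b1, b1), hidden))
  m$params$w2 <- mk_param(matrix(stats::runif(c * hidden, -b2, b2), c))
  m$gate <- function(x) {
    z <- op_gap(x)
    op_sigmoid(op_dense(op_relu(op_dense(z, m$params$w1)), m$params$w2))
  }
  m$forward <- function(x, training = FALSE) op_cmul(x, m$gate(x))
  m
}

# CBAM channel attention: shared MLP over avg- and max-pooled descriptors
cbam_channel_layer <- function(c, reduction = 16L) {
  m <- new_module("cbam_ca")
  hidden <- max(1L, c %/% reduction)
  b1 <- sqrt(6 / c); b2 <- sqrt(6 / hidden)
  m$params$w1 <- mk_param(matrix(stats::runif(hidden * c, -b1, b1), hidden))
  m$params$w2 <- mk_param(matrix(stats::runif(c * hidden, -b2, b2), c))
  m$weights <- function(x) {
    mlp <- function(z) op_dense(op_relu(op_dense(z, m$params$w1)),
                                m$params$w2)
    op_sigmoid(op_add(mlp(op_gap(x)), mlp(op_gmp(x))))
  }
  m$forward <- function(x, training = FALSE) op_cmul(x, m$weights(x))
  m
}

# CBAM spatial attention: stack channel-mean and channel-max, 7x7 conv,
# sigmoid -> (1,H,W,N) gate
spatial_attn_layer <- function(k = 7L) {
  m <- new_module("cbam_sa")
  m$children$conv <- conv_layer(2L, 1L, k, 1L, k %/% 2L, bias = TRUE)
  m$map <- function(x, training = FALSE) {
    stacked <- op_concat(list(op_chan_mean(x), op_chan_max(x)))
    op_sigmoid(m$children$conv$forward(stacked, training))
  }
  m$forward <- function(x, training = FALSE) op_smul(x, m$map(x, training))
  m
}

# standard residual bottleneck used inside C3
bottleneck_layer <- function(c1, c2, shortcut = TRUE) {
  m <- new_module("bottleneck")
  m$children$cv1 <- cba_layer(c1, c2, 1L)
  m$children$cv2 <- cba_layer(c2, c2, 3L)
  m$shortcut <- shortcut && c1 == c2
  m$forward <- function(x, training = FALSE) {
    y <- m$children$cv2$forward(m$children$cv1$forward(x, training), training)
    if (m$shortcut) op_add(x, y) else y
  }
  m
}

# CSP C3 stage; when `use_clab` the bottlenecks are cross-layer attention
# bottlenecks threading a stage-local spatial-attention history
c3_layer <- function(c1, c2, n = 1L, shortcut = TRUE, use_clab = FALSE,
                     reduction = 16L) {
  m <- new_module("c3")
  c_ <- c2 %/% 2L
  m$children$cv1 <- cba_layer(c1, c_, 1L)
  m$children$cv2 <- cba_layer(c1, c_, 1L)
  m$children$cv3 <- cba_layer(2L * c_, c2, 1L)
  m$n <- n
  m$use_clab <- use_clab
  for (i in seq_len(n)) {
    nm <- paste0("m", i)
    m$children[[nm]] <- if (use_clab)
      clab_bottleneck_layer(c_, c_, layer_index = i, shortcut = shortcut,
                            reduction = reduction)
    else bottleneck_layer(c_, c_, shortcut)
  }
  m$forward <- function(x, training = FALSE) {
    y <- m$children$cv1$forward(x, training)
    if (m$use_clab) {
      history <- list()  # stage-local: starts empty in every stage
      for (i in seq_len(m$n)) {
        r <- m$children[[paste0("m", i)]]$forward_hist(y, history, training)
        y <- r$out
        history <- r$history
      }
    } else {
      for (i in seq_len(m$n))
        y <- m$children[[paste0("m", i)]]$forward(y, training)
    }
    z <- m$children$cv2$forward(x, training)
    m$children$cv3$forward(op_concat(list(y, z)), training)
  }
  m
}

# SPPF: three stacked 5x5 max-pools concatenated with the input
sppf_layer <- function(c1, c2, k = 5L) {
  m <- new_module("sppf")
  c_ <- c1 %/% 2L
  m$children$cv1 <- cba_layer(c1, c_, 1L)
  m$children$cv2 <- cba_layer(c_ * 4L, c2, 1L)
  m$k <- k
  m$forward <- function(x, training = FALSE) {
    x <- m$children$cv1$forward(x, training)
    y1 <- op_maxpool(x, m$k, 1L, m$k %/% 2L)
    y2 <- op_maxpool(y1, m$k, 1L, m$k %/% 2L)
    y3 <- op_maxpool(y2, m$k, 1L, m$k %/% 2L)
    m$children$cv2$forward(op_concat(list(x, y1, y2, y3)), training)
  }
  m
}

as_feature_map <- function(x) {
  if (is_tensor(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) stop("feature maps must be C x H x W")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  yb_tensor(x)
}

fm_value <- function(t) {
  v <- t$v
  d <- dim(v)
  if (length(d) == 4L && d[4] == 1L) dim(v) <- d[1:3]
  v
}
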