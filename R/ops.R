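# Differentiable tensor operations.
#
# Feature maps are numeric arrays with dim (C, H, W, N); channel vectors are
# (C, N) matrices; token sequences are (T, d, N) arrays.  Every op optionally
# accumulates multiply-accumulate counts for profiling: convolutions and
# matrix products count exactly, and every elementwise arithmetic result
# element counts as one MAC (batch norm scale-shift, activations, gates).
# Reductions, pooling, concatenation and reshapes count zero.

# ---- helpers ------------------------------------------------------------

yb_dims <- function(x) {
  d <- dim(x)
  if (is.null(d)) c(length(x), 1L) else d
}

# expand a (C,N) channel matrix to a plain (C*H*W*N) vector in map layout
expand_chan <- function(s, C, HW, N) {
  s <- matrix(s, nrow = C)
  as.numeric(s[, rep(seq_len(N), each = HW), drop = FALSE])
}

# expand a (1,H,W,N) spatial map over C channels
expand_spat <- function(m, C) rep(as.numeric(m), each = C)

# per-(channel, image) sums of a (C,H,W,N)-shaped vector
chan_sums <- function(v, C, HW, N) {
  m <- matrix(v, nrow = C)
  out <- matrix(0, C, N)
  for (n in seq_len(N))
    out[, n] <- rowSums(m[, ((n - 1) * HW + 1):(n * HW), drop = FALSE])
  out
}

# ---- convolution --------------------------------------------------------

# w: (C2, C1*k*k) matrix, patch order channel-fastest (matches cpp_im2col)
op_conv2d <- function(x, w, b = NULL, k = 1L, stride = 1L, pad = 0L) {
  d <- dim(x$v)
  C1 <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  C2 <- nrow(w$v)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  pointwise <- k == 1L && stride == 1L && pad == 0L
  col <- if (pointwise) {
    cm <- x$v
    dim(cm) <- c(C1, H * W * N)
    cm
  } else {
    cpp_im2col(x$v, as.integer(d), as.integer(k), as.integer(stride),
               as.integer(pad))
  }
  out <- w$v %*% col
  yb_add_macs(as.numeric(C1) * k * k * C2 * Ho * Wo * N)
  if (!is.null(b)) {
    out <- out + b$v
    yb_add_macs(as.numeric(C2) * Ho * Wo * N)
  }
  dim(out) <- c(C2, Ho, Wo, N)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  yb_op(out, parents, function(g) {
    gm <- matrix(g, nrow = C2)
    dw <- tcrossprod(gm, col)
    dcol <- crossprod(w$v, gm)
    dx <- if (pointwise) {
      dim(dcol) <- d
      dcol
    } else {
      cpp_col2im(dcol, as.integer(d), as.integer(k), as.integer(stride),
                 as.integer(pad))
    }
    if (is.null(b)) list(dx, dw) else list(dx, dw, rowSums(gm))
  })
}

# ---- batch norm ---------------------------------------------------------

# Training-mode statistics are computed over (H,W,N).  `stats_out`, when an
# environment, receives the batch mean/var so the module can update running
# statistics without entering the tape.
op_batchnorm <- function(x, gamma, beta, rm, rv, training = FALSE,
                         eps = 1e-3, stats_out = NULL) {
  d <- dim(x$v)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]; M <- HW * N
  xm <- matrix(x$v, nrow = C)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
    va <- pmax(va, 0)
    if (is.environment(stats_out)) {
      stats_out$mean <- mu
      stats_out$var <- va * M / max(M - 1, 1)
    }
  } else {
    mu <- rm
    va <- rv
  }
  istd <- 1 / sqrt(va + eps)
  # per-channel vectors recycle along the first dimension of (C, HW*N)
  xhat <- (xm - mu) * istd
  out <- xhat * gamma$v + beta$v
  dim(out) <- d
  yb_add_macs(as.numeric(prod(d)))
  yb_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = C)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gamma$v
    if (training) {
      dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
        istd
    } else {
      dx <- dxhat * istd
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# ---- activations --------------------------------------------------------

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  yb_add_macs(as.numeric(length(s)))
  yb_op(s, list(x), function(g) list(g * s * (1 - s)))
}

op_silu <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  out <- x$v * s
  yb_add_macs(as.numeric(length(s)))
  yb_op(out, list(x), function(g) list(g * s * (1 + x$v * (1 - s))))
}

op_relu <- function(x) {
  out <- pmax(x$v, 0)
  if (!is.null(dim(x$v))) dim(out) <- dim(x$v)
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x), function(g) list(g * (x$v > 0)))
}

# ---- elementwise --------------------------------------------------------

op_add <- function(x, y) {
  out <- x$v + y$v
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x, y), function(g) list(g, g))
}

op_sub <- function(x, y) {
  out <- x$v - y$v
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x, y), function(g) list(g, -g))
}

op_mul <- function(x, y) {
  out <- x$v * y$v
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x, y), function(g) list(g * y$v, g * x$v))
}

op_div <- function(x, y) {
  out <- x$v / y$v
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x, y),
        function(g) list(g / y$v, -g * x$v / (y$v * y$v)))
}

# a*x + b with numeric constants
op_affine <- function(x, a = 1, b = 0) {
  out <- a * x$v + b
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x), function(g) list(a * g))
}

op_square <- function(x) {
  out <- x$v * x$v
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x), function(g) list(2 * g * x$v))
}

op_sqrt <- function(x, eps = 1e-12) {
  out <- sqrt(pmax(x$v, eps))
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x), function(g) list(g * 0.5 / out))
}

op_atan <- function(x) {
  out <- atan(x$v)
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x), function(g) list(g / (1 + x$v * x$v)))
}

op_pmin <- function(x, y) {
  take_x <- x$v <= y$v
  out <- ifelse(take_x, x$v, y$v)
  if (!is.null(dim(x$v))) dim(out) <- dim(x$v)
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x, y), function(g) list(g * take_x, g * !take_x))
}

op_pmax <- function(x, y) {
  take_x <- x$v >= y$v
  out <- ifelse(take_x, x$v, y$v)
  if (!is.null(dim(x$v))) dim(out) <- dim(x$v)
  yb_add_macs(as.numeric(length(out)))
  yb_op(out, list(x, y), function(g) list(g * take_x, g * !take_x))
}

# ---- broadcasting gates -------------------------------------------------

# multiply (C,H,W,N) by per-channel weights s: (C,N)
op_cmul <- function(x, s) {
  d <- dim(x$v)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  se <- expand_chan(s$v, C, HW, N)
  out <- x$v * se
  dim(out) <- d
  yb_add_macs(as.numeric(prod(d)))
  yb_op(out, list(x, s), function(g) {
    dx <- g * se
    dim(dx) <- d
    ds <- chan_sums(as.numeric(g) * as.numeric(x$v), C, HW, N)
    if (is.null(dim(s$v))) ds <- as.numeric(ds)
    list(dx, ds)
  })
}

# multiply (C,H,W,N) by a single-channel spatial map m: (1,H,W,N)
op_smul <- function(x, m) {
  d <- dim(x$v)
  C <- d[1]
  me <- expand_spat(m$v, C)
  out <- x$v * me
  dim(out) <- d
  yb_add_macs(as.numeric(prod(d)))
  yb_op(out, list(x, m), function(g) {
    dx <- g * me
    dim(dx) <- d
    dm <- colSums(matrix(as.numeric(g) * as.numeric(x$v), nrow = C))
    dim(dm) <- dim(m$v)
    list(dx, dm)
  })
}

# ---- shape ops ----------------------------------------------------------

op_concat <- function(xs) {
  ds <- lapply(xs, function(t) dim(t$v))
  Cs <- vapply(ds, `[`, 0, 1)
  d1 <- ds[[1]]
  Ctot <- sum(Cs)
  out <- array(0, c(Ctot, d1[2], d1[3], d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[(at + 1):(at + Cs[i]), , , ] <- xs[[i]]$v
    at <- at + Cs[i]
  }
  yb_op(out, xs, function(g) {
    gs <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      gi <- g[(at + 1):(at + Cs[i]), , , , drop = FALSE]
      dim(gi) <- ds[[i]]
      gs[[i]] <- gi
      at <- at + Cs[i]
    }
    gs
  })
}

# (C,H,W,N) -> (T,C,N) token sequence, T = H*W in column-major (h fastest)
op_tokens <- function(x) {
  d <- dim(x$v)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  out <- aperm(array(x$v, c(C, HW, N)), c(2, 1, 3))
  yb_op(out, list(x), function(g) {
    dx <- aperm(g, c(2, 1, 3))
    dim(dx) <- d
    list(dx)
  })
}

# (T,C,N) -> (C,H,W,N)
op_untokens <- function(x, H, W) {
  d <- dim(x$v)
  out <- aperm(x$v, c(2, 1, 3))
  dim(out) <- c(d[2], H, W, d[3])
  yb_op(out, list(x), function(g) {
    dim(g) <- c(d[2], d[1], d[3])
    list(aperm(g, c(2, 1, 3)))
  })
}

op_gather <- function(x, idx) {
  d <- dim(x$v)
  out <- matrix(x$v[idx], ncol = 1)
  yb_op(out, list(x), function(g) {
    dx <- array(0, d)
    # scatter-add (idx may repeat across anchors in principle)
    tt <- tapply(as.numeric(g), idx, sum)
    dx[as.numeric(names(tt))] <- tt
    list(dx)
  })
}

# ---- pooling / resampling ----------------------------------------------

op_maxpool <- function(x, k, stride = 1L, pad = 0L) {
  d <- dim(x$v)
  r <- cpp_maxpool(x$v, as.integer(d), as.integer(k), as.integer(stride),
                   as.integer(pad))
  yb_op(r$out, list(x), function(g)
    list(cpp_maxpool_bwd(as.numeric(g), r$argmax, as.integer(d))))
}

op_upsample2 <- function(x) {
  d <- dim(x$v)
  H <- d[2]; W <- d[3]
  out <- x$v[, rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), ,
             drop = FALSE]
  yb_op(out, list(x), function(g) {
    oh <- seq(1, 2 * H, by = 2)
    ow <- seq(1, 2 * W, by = 2)
    dx <- g[, oh, , , drop = FALSE] + g[, oh + 1, , , drop = FALSE]
    dx <- dx[, , ow, , drop = FALSE] + dx[, , ow + 1, , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

op_pixel_shuffle <- function(x, r) {
  d <- dim(x$v)
  out <- cpp_pixel_shuffle(x$v, as.integer(d), as.integer(r))
  yb_op(out, list(x), function(g)
    list(cpp_pixel_unshuffle(as.numeric(g), as.integer(dim(out)),
                             as.integer(r))))
}

op_adaptive_avgpool <- function(x, Ho, Wo) {
  d <- dim(x$v)
  out <- cpp_adaptive_avgpool(x$v, as.integer(d), as.integer(Ho),
                              as.integer(Wo))
  yb_op(out, list(x), function(g)
    list(cpp_adaptive_avgpool_bwd(as.numeric(g), as.integer(d),
                                  as.integer(Ho), as.integer(Wo))))
}

# global average pool over (H,W): (C,H,W,N) -> (C,N)
op_gap <- function(x) {
  d <- dim(x$v)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  m3 <- array(x$v, c(C, HW, N))
  out <- matrix(0, C, N)
  for (n in seq_len(N)) out[, n] <- rowMeans(m3[, , n, drop = FALSE])
  yb_op(out, list(x), function(g) {
    dx <- expand_chan(g / HW, C, HW, N)
    dim(dx) <- d
    list(dx)
  })
}

# global max pool over (H,W): (C,H,W,N) -> (C,N)
op_gmp <- function(x) {
  d <- dim(x$v)
  r <- cpp_gmp(x$v, as.integer(d))
  yb_op(r$out, list(x), function(g) {
    dx <- array(0, d)
    dx[as.numeric(r$argmax)] <- dx[as.numeric(r$argmax)] + as.numeric(g)
    list(dx)
  })
}

# mean over channels: (C,H,W,N) -> (1,H,W,N)
op_chan_mean <- function(x) {
  d <- dim(x$v)
  C <- d[1]
  out <- colMeans(matrix(x$v, nrow = C))
  dim(out) <- c(1L, d[2], d[3], d[4])
  yb_op(out, list(x), function(g) {
    dx <- rep(as.numeric(g) / C, each = C)
    dim(dx) <- d
    list(dx)
  })
}

# max over channels: (C,H,W,N) -> (1,H,W,N)
op_chan_max <- function(x) {
  d <- dim(x$v)
  r <- cpp_chanmax(x$v, as.integer(d))
  yb_op(r$out, list(x), function(g) {
    dx <- array(0, d)
    dx[as.numeric(r$argmax)] <- dx[as.numeric(r$argmax)] + as.numeric(g)
    list(dx)
  })
}

# ---- dense / attention --------------------------------------------------

# z: (Cin,N), w: (Cout,Cin), b: optional (Cout)
op_dense <- function(z, w, b = NULL) {
  zv <- if (is.null(dim(z$v))) matrix(z$v, ncol = 1) else z$v
  out <- w$v %*% zv
  yb_add_macs(as.numeric(nrow(w$v)) * ncol(w$v) * ncol(zv))
  if (!is.null(b)) {
    out <- out + b$v
    yb_add_macs(as.numeric(length(out)))
  }
  parents <- if (is.null(b)) list(z, w) else list(z, w, b)
  yb_op(out, parents, function(g) {
    dz <- crossprod(w$v, g)
    dw <- g %*% t(zv)
    if (is.null(b)) list(dz, dw) else list(dz, dw, rowSums(g))
  })
}

# batched matmul: A (a,b,N) x B (b,c,N) -> (a,c,N)
op_bmm <- function(A, B, transpose_b = FALSE) {
  da <- dim(A$v); db <- dim(B$v)
  N <- da[3]
  bk <- if (transpose_b) db[2] else db[1]
  cc <- if (transpose_b) db[1] else db[2]
  out <- array(0, c(da[1], cc, N))
  for (n in seq_len(N)) {
    out[, , n] <- if (transpose_b) tcrossprod(A$v[, , n], B$v[, , n])
                  else A$v[, , n] %*% B$v[, , n]
  }
  yb_add_macs(as.numeric(da[1]) * bk * cc * N)
  yb_op(out, list(A, B), function(g) {
    dA <- array(0, da); dB <- array(0, db)
    for (n in seq_len(N)) {
      if (transpose_b) {
        dA[, , n] <- g[, , n] %*% B$v[, , n]
        dB[, , n] <- crossprod(g[, , n], A$v[, , n])
      } else {
        dA[, , n] <- tcrossprod(g[, , n], B$v[, , n])
        dB[, , n] <- crossprod(A$v[, , n], g[, , n])
      }
    }
    list(dA, dB)
  })
}

# row-wise softmax of (a,b,N) over columns b
op_softmax_rows <- function(x) {
  d <- dim(x$v)
  out <- array(0, d)
  for (n in seq_len(d[3])) {
    m <- x$v[, , n, drop = FALSE]
    dim(m) <- d[1:2]
    rmax <- m[cbind(seq_len(d[1]), max.col(m, ties.method = "first"))]
    m <- exp(m - rmax)
    out[, , n] <- m / rowSums(m)
  }
  yb_add_macs(2 * as.numeric(prod(d)))
  yb_op(out, list(x), function(g) {
    dx <- array(0, d)
    for (n in seq_len(d[3])) {
      p <- out[, , n, drop = FALSE]; dim(p) <- d[1:2]
      gn <- g[, , n, drop = FALSE]; dim(gn) <- d[1:2]
      dx[, , n] <- p * (gn - rowSums(p * gn))
    }
    list(dx)
  })
}

# ---- reductions / losses ------------------------------------------------

op_sum <- function(x) {
  out <- sum(x$v)
  d <- yb_dims(x$v)
  yb_op(out, list(x), function(g) {
    dx <- array(as.numeric(g), d)
    if (is.null(dim(x$v))) dx <- as.numeric(dx)
    list(dx)
  })
}

op_mean <- function(x) {
  n <- length(x$v)
  out <- sum(x$v) / n
  d <- yb_dims(x$v)
  yb_op(out, list(x), function(g) {
    dx <- array(as.numeric(g) / n, d)
    if (is.null(dim(x$v))) dx <- as.numeric(dx)
    list(dx)
  })
}

# binary cross-entropy with logits; target and weight are plain numerics.
# Returns the weighted sum of elementwise losses.
op_bce_logits <- function(x, target, weight = NULL) {
  z <- x$v
  # stable: max(z,0) - z*t + log(1+exp(-|z|))
  l <- pmax(z, 0) - z * target + log1p(exp(-abs(z)))
  if (!is.null(weight)) l <- l * weight
  out <- sum(l)
  yb_add_macs(3 * as.numeric(length(z)))
  yb_op(out, list(x), function(g) {
    s <- 1 / (1 + exp(-z))
    dx <- (s - target)
    if (!is.null(weight)) dx <- dx * weight
    dx <- as.numeric(g) * dx
    if (!is.null(dim(x$v))) dim(dx) <- dim(x$v)
    list(dx)
  })
}

# ---- fused multi-kernel convolution ------------------------------------

# Five parallel same-padding convolutions with kernels k1 < ... < kmax can
# share one im2col at kmax: each smaller kernel embeds centered in a kmax
# patch with a zero border, which is mathematically identical to its own
# padded convolution. MACs are counted for the logical (unfused) branches.
op_conv2d_multi <- function(x, ws, bs, kernels) {
  d <- dim(x$v)
  C1 <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  kmax <- max(kernels)
  pad <- kmax %/% 2L
  col <- cpp_im2col(x$v, as.integer(d), as.integer(kmax), 1L,
                    as.integer(pad))
  outs_c <- vapply(ws, function(w) nrow(w$v), 0L)
  emb <- matrix(0, sum(outs_c), C1 * kmax * kmax)
  dst_idx <- vector("list", length(kernels))
  at <- 0L
  for (i in seq_along(kernels)) {
    k <- kernels[i]
    off <- (kmax - k) %/% 2L
    ky <- rep(0:(k - 1L), each = k)
    kx <- rep(0:(k - 1L), times = k)
    base <- ((ky + off) * kmax + (kx + off)) * C1
    dst <- as.integer(outer(seq_len(C1), base, `+`))
    dst_idx[[i]] <- dst
    emb[at + seq_len(outs_c[i]), dst] <- ws[[i]]$v
    at <- at + outs_c[i]
    yb_add_macs(as.numeric(C1) * k * k * outs_c[i] * H * W * N)
  }
  bias <- unlist(lapply(bs, function(b) b$v))
  out <- emb %*% col + bias
  yb_add_macs(as.numeric(length(out)))
  dim(out) <- c(sum(outs_c), H, W, N)
  parents <- c(list(x), ws, bs)
  yb_op(out, parents, function(g) {
    gm <- matrix(g, nrow = sum(outs_c))
    demb <- tcrossprod(gm, col)
    dcol <- crossprod(emb, gm)
    dx <- cpp_col2im(dcol, as.integer(d), as.integer(kmax), 1L,
                     as.integer(pad))
    grads <- vector("list", 1L + 2L * length(ws))
    grads[[1L]] <- dx
    at <- 0L
    for (i in seq_along(ws)) {
      rows <- at + seq_len(outs_c[i])
      grads[[1L + i]] <- demb[rows, dst_idx[[i]], drop = FALSE]
      grads[[1L + length(ws) + i]] <- rowSums(gm[rows, , drop = FALSE])
      at <- at + outs_c[i]
    }
    grads
  })
}
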