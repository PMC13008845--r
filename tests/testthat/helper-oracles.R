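# Shared fixtures and independent scalar oracles.

rt <- function(..., sd = 1) {
  d <- c(...)
  array(stats::rnorm(prod(d), sd = sd), d)
}

tensor_of <- function(v) yolobt:::yb_tensor(v, requires_grad = TRUE)

# direct scalar 2-D convolution oracle: x (C1,H,W), w (C2, C1*k*k) in the
# package's patch order (channel fastest, then kx, then ky), zero padding
conv2d_oracle <- function(x, w, b = NULL, k = 1, stride = 1, pad = 0) {
  d <- dim(x)
  C1 <- d[1]; H <- d[2]; W <- d[3]
  C2 <- nrow(w)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(C2, Ho, Wo))
  for (c2 in seq_len(C2))
    for (ho in seq_len(Ho))
      for (wo in seq_len(Wo)) {
        acc <- 0
        for (ky in seq_len(k))
          for (kx in seq_len(k))
            for (c1 in seq_len(C1)) {
              hin <- (ho - 1) * stride - pad + ky
              win <- (wo - 1) * stride - pad + kx
              if (hin >= 1 && hin <= H && win >= 1 && win <= W) {
                wi <- (ky - 1) * k * C1 + (kx - 1) * C1 + c1
                acc <- acc + w[c2, wi] * x[c1, hin, win]
              }
            }
        out[c2, ho, wo] <- acc + if (is.null(b)) 0 else b[c2]
      }
  out
}

# scalar SE oracle over a (C,H,W) map: Eqs: z_c = mean; s = sig(W2 relu(W1 z));
# out = s_c * x
se_oracle <- function(x, w1, w2) {
  C <- dim(x)[1]
  z <- vapply(seq_len(C), function(c) mean(x[c, , ]), 0)
  h <- pmax(w1 %*% z, 0)
  s <- 1 / (1 + exp(-(w2 %*% h)))
  out <- x
  for (c in seq_len(C)) out[c, , ] <- s[c] * x[c, , ]
  list(s = as.numeric(s), out = out)
}

# finite-difference check of the gradient w.r.t. each tensor in `wrt`
# through scalar-valued f(); returns max abs rel error
fd_check <- function(f, wrt, eps = 1e-5) {
  loss <- yolobt:::yb_with_grad(f())
  for (p in wrt) p$g <- NULL
  yolobt:::yb_backward(loss)
  worst <- 0
  for (p in wrt) {
    ga <- p$g
    if (is.null(ga)) ga <- array(0, length(p$v))
    n <- length(p$v)
    pick <- if (n > 6) sample(n, 6) else seq_len(n)
    for (i in pick) {
      old <- p$v[i]
      p$v[i] <- old + eps
      up <- yolobt:::yb_no_grad(f())$v
      p$v[i] <- old - eps
      dn <- yolobt:::yb_no_grad(f())$v
      p$v[i] <- old
      num <- (up - dn) / (2 * eps)
      err <- abs(num - ga[i]) / max(1e-4, abs(num), abs(ga[i]))
      worst <- max(worst, err)
    }
  }
  worst
}

# tiny screen config for fast generator tests
tiny_config <- function(n_channels = 8L, ...) {
  gen_config(n_channels = n_channels, sfreq = 100, trial_len = 0.5, ...)
}

box_row <- function(cx, w = 0.1, cy = 0.5, h = 1, cls = 0) {
  matrix(c(cls, cx, cy, w, h), 1,
         dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
}

# exhaustive threshold-sweep AP oracle: for every distinct confidence
# threshold compute P and R from scratch and accumulate the printed sum
ap_oracle <- function(det_tp, conf, n_truth) {
  if (!length(conf) || n_truth == 0) return(0)
  thr <- sort(unique(conf), decreasing = TRUE)
  prevR <- 0; ap <- 0
  for (t in thr) {
    keep <- conf >= t
    P <- sum(det_tp[keep]) / sum(keep)
    R <- sum(det_tp[keep]) / n_truth
    ap <- ap + (R - prevR) * P
    prevR <- R
  }
  ap
}
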