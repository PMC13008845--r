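# Minimal tape-based reverse-mode autodiff over plain R arrays.
#
# A "yb_tensor" is an environment holding the value (`v`), the accumulated
# gradient (`g`), the parent tensors and a backward closure mapping the
# output gradient to a list of parent gradients.  Ops record onto the tape
# only while grad mode is on (see `yb_no_grad()`), so inference and
# profiling run without building a graph.

.yb <- new.env(parent = emptyenv())
.yb$grad_on <- FALSE
.yb$count_macs <- FALSE
.yb$macs <- 0
.yb$next_id <- 1L

yb_add_macs <- function(n) {
  if (.yb$count_macs) .yb$macs <- .yb$macs + n
  invisible(NULL)
}

#' Run an expression with gradient recording enabled
#'
#' @param expr expression to evaluate with the tape active
#' @return value of `expr`
#' @keywords internal
yb_with_grad <- function(expr) {
  old <- .yb$grad_on
  .yb$grad_on <- TRUE
  on.exit(.yb$grad_on <- old)
  force(expr)
}

#' Run an expression with gradient recording disabled
#' @inheritParams yb_with_grad
#' @keywords internal
yb_no_grad <- function(expr) {
  old <- .yb$grad_on
  .yb$grad_on <- FALSE
  on.exit(.yb$grad_on <- old)
  force(expr)
}

#' Create a tensor
#'
#' @param v numeric array/matrix/vector value
#' @param requires_grad should gradients accumulate into this tensor?
#' @return a `yb_tensor`
#' @keywords internal
yb_tensor <- function(v, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$parents <- list()
  e$bw <- NULL
  e$rg <- requires_grad
  e$id <- .yb$next_id
  .yb$next_id <- .yb$next_id + 1L
  class(e) <- "yb_tensor"
  e
}

is_tensor <- function(x) inherits(x, "yb_tensor")

#' @export
print.yb_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<yb_tensor", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$rg) "grad" else "", ">\n")
  invisible(x)
}

# Register an op result on the tape. `bw` takes the output gradient and
# returns a list of gradients aligned with `parents` (NULL entries allowed).
yb_op <- function(v, parents, bw) {
  t <- yb_tensor(v)
  if (.yb$grad_on) {
    live <- any(vapply(parents, function(p) p$rg || !is.null(p$bw), TRUE))
    if (live) {
      t$parents <- parents
      t$bw <- bw
    }
  }
  t
}

#' Reverse-mode backward pass
#'
#' Accumulates gradients of `root` (a scalar unless `grad` is given) into
#' every reachable tensor with `requires_grad = TRUE`.
#'
#' @param root output tensor
#' @param grad gradient seed; defaults to 1 for scalars
#' @keywords internal
yb_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    stopifnot(length(root$v) == 1L)
    grad <- array(1, dim = if (is.null(dim(root$v))) 1L else dim(root$v))
  }
  # iterative topological sort
  order <- vector("list", 256L)
  norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", norder))
      order[[norder]] <- nd
    }
  }
  root$g <- grad
  for (i in seq_len(norder)) {
    nd <- order[[norder - i + 1L]]
    if (is.null(nd$bw) || is.null(nd$g)) next
    gs <- nd$bw(nd$g)
    for (j in seq_along(nd$parents)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- nd$parents[[j]]
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
    if (!identical(nd, root)) nd$g <- NULL  # free intermediate grads
  }
  invisible(root)
}

yb_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}
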