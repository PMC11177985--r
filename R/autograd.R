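# Minimal reverse-mode autodiff tape for the CNN engine.
#
# Values are R arrays [H, W, C, N]. A tape records operations in execution
# order; ag_backward() seeds an output node with a gradient array and sweeps
# the tape in reverse, accumulating gradients into tracked nodes (parameters).
# Heavy kernels (convolutions, pooling) are C++ (src/cnn_kernels.cpp).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(val, track = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$track <- track
  nd
}

#' @noRd
ag_const <- function(val) ag_node(val, track = FALSE)
ag_param <- function(val) ag_node(val, track = TRUE)

ag_push <- function(tp, out, inputs, bw) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$ops)) tp$ops <- c(tp$ops, vector("list", length(tp$ops)))
  tp$ops[[tp$n]] <- list(out = out, inputs = inputs, bw = bw)
  out
}

ag_op <- function(tp, val, inputs, bw) {
  track <- any(vapply(inputs, function(x) isTRUE(x$track), logical(1)))
  out <- ag_node(val, track = track)
  if (track) ag_push(tp, out, inputs, bw)
  out
}

.acc_grad <- function(nd, g) {
  if (!isTRUE(nd$track)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' Run the reverse sweep of a tape
#'
#' @param tp tape from `ag_tape()`
#' @param out output node whose gradient is seeded
#' @param grad gradient array of the scalar objective w.r.t. `out$val`
#' @noRd
ag_backward <- function(tp, out, grad) {
  out$grad <- grad
  if (tp$n == 0L) return(invisible(NULL))
  for (k in seq(tp$n, 1L)) {
    op <- tp$ops[[k]]
    g <- op$out$grad
    if (is.null(g)) next
    gs <- op$bw(g)
    for (i in seq_along(op$inputs)) {
      if (!is.null(gs[[i]])) .acc_grad(op$inputs[[i]], gs[[i]])
    }
    op$out$grad <- NULL  # free
  }
  invisible(NULL)
}

# ---- operations ------------------------------------------------------------

#' 2-D convolution node
#' @param pad integer(4): top, bottom, left, right
#' @noRd
ag_conv2d <- function(tp, x, w, b, stride = 1L, pad = c(1L, 1L, 1L, 1L)) {
  y <- conv2d_fw_cpp(x$val, w$val, b$val, as.integer(stride),
                     pad[1], pad[2], pad[3], pad[4])
  xv <- x$val; wv <- w$val
  ag_op(tp, y, list(x, w, b), function(g) {
    r <- conv2d_bw_cpp(xv, wv, g, as.integer(stride),
                       pad[1], pad[2], pad[3], pad[4])
    list(r$dx, r$dw, r$db)
  })
}

ag_convt2x2 <- function(tp, x, w, b) {
  y <- convt2x2_fw_cpp(x$val, w$val, b$val)
  xv <- x$val; wv <- w$val
  ag_op(tp, y, list(x, w, b), function(g) {
    r <- convt2x2_bw_cpp(xv, wv, g)
    list(r$dx, r$dw, r$db)
  })
}

ag_maxpool2 <- function(tp, x) {
  r <- maxpool2_fw_cpp(x$val)
  d <- dim(x$val)
  ag_op(tp, r$y, list(x), function(g) {
    list(maxpool2_bw_cpp(g, r$idx, d[1], d[2]))
  })
}

ag_relu <- function(tp, x) {
  m <- x$val > 0
  y <- x$val * m
  ag_op(tp, y, list(x), function(g) list(g * m))
}

ag_leaky_relu <- function(tp, x, slope = 0.01) {
  m <- x$val > 0
  y <- ifelse(m, x$val, slope * x$val)
  dim(y) <- dim(x$val)
  ag_op(tp, y, list(x), function(g) list(g * ifelse(m, 1, slope)))
}

ag_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$val))
  ag_op(tp, y, list(x), function(g) list(g * y * (1 - y)))
}

ag_add <- function(tp, x, y) {
  ag_op(tp, x$val + y$val, list(x, y), function(g) list(g, g))
}

#' Concatenate along the channel dimension
#' @noRd
ag_concat_c <- function(tp, x, y) {
  dx <- dim(x$val); dy <- dim(y$val)
  stopifnot(all(dx[c(1, 2, 4)] == dy[c(1, 2, 4)]))
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$val
  v[, , dx[3] + seq_len(dy[3]), ] <- y$val
  ag_op(tp, v, list(x, y), function(g) {
    list(g[, , seq_len(dx[3]), , drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

#' Multiply every channel of x by a single-channel map a ([H,W,1,N])
#' @noRd
ag_scale_channels <- function(tp, x, a) {
  C <- dim(x$val)[3]
  arep <- a$val[, , rep(1L, C), , drop = FALSE]
  y <- x$val * arep
  xv <- x$val
  ag_op(tp, y, list(x, a), function(g) {
    da <- apply(g * xv, c(1, 2, 4), sum)
    dim(da) <- dim(a$val)
    list(g * arep, da)
  })
}

#' Batch normalization over (H, W, N) per channel
#'
#' `state` is an environment holding running_mean / running_var, updated by
#' side effect in training mode; inference mode uses the running statistics.
#' @noRd
ag_batchnorm <- function(tp, x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val)
  C <- d[3]
  m <- prod(d[c(1, 2, 4)])
  if (training) {
    mu <- apply(x$val, 3, mean)
    va <- apply(x$val, 3, function(v) mean((v - mean(v))^2))
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  mu_a <- rep(mu, each = prod(d[1:2]))
  sd_a <- rep(sqrt(va + eps), each = prod(d[1:2]))
  xhat <- sweep_cn(x$val, mu_a, sd_a)
  g_a <- rep(as.vector(gamma$val), each = prod(d[1:2]))
  y <- xhat * rep_cn(g_a, d) + rep_cn(rep(as.vector(beta$val), each = prod(d[1:2])), d)
  ag_op(tp, y, list(x, gamma, beta), function(g) {
    dgamma <- apply(g * xhat, 3, sum)
    dbeta <- apply(g, 3, sum)
    if (training) {
      mdy <- apply(g, 3, mean)
      mdyx <- apply(g * xhat, 3, mean)
      dx <- (rep_cn(g_a, d) / rep_cn(sd_a, d)) *
        (g - rep_cn(rep(mdy, each = prod(d[1:2])), d) -
           xhat * rep_cn(rep(mdyx, each = prod(d[1:2])), d))
    } else {
      dx <- g * rep_cn(g_a, d) / rep_cn(sd_a, d)
    }
    list(dx, dgamma, dbeta)
  })
}

# broadcast helpers: values laid out per (H*W, C) tile replicated across N
sweep_cn <- function(x, mu_a, sd_a) {
  d <- dim(x)
  xv <- array(x, c(prod(d[1:3]), d[4]))
  out <- (xv - mu_a) / sd_a
  dim(out) <- d
  out
}

rep_cn <- function(v_a, d) {
  out <- array(v_a, c(prod(d[1:3]), d[4]))
  dim(out) <- d
  out
}
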