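# Minimal convolutional network engine.
#
# Every other component of the audit (the classifier family, Expected
# Gradients, the cycle-consistent translators) needs forward passes,
# parameter gradients AND gradients with respect to the input image, so the
# engine exposes all three. Images are H x W x C arrays; a network is an
# environment holding a list of layer environments, each with its own
# parameters, accumulated gradients and momentum buffers. All convolutions
# are 3x3 (or kxk odd), stride 1, "same" zero padding; spatial downsampling
# is done by 2x2 average pooling. This keeps the backward pass simple enough
# to verify exhaustively by finite differences (see tests).

#' Create a convolutional layer
#'
#' Weights use He initialisation, `rnorm * sqrt(2 / fan_in)`; draw order is
#' fixed so layers are reproducible under a set seed.
#'
#' @param in_ch,out_ch input/output channel counts.
#' @param k odd kernel size (default 3); stride 1, zero "same" padding.
#' @param frozen if TRUE the optimiser never updates this layer.
#' @return a layer environment.
#' @keywords internal
#' @export
nn_conv <- function(in_ch, out_ch, k = 3L, frozen = FALSE) {
  stopifnot(k %% 2L == 1L)
  fan_in <- k * k * in_ch
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$k <- as.integer(k)
  l$in_ch <- as.integer(in_ch)
  l$out_ch <- as.integer(out_ch)
  l$W <- matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                fan_in, out_ch)
  l$b <- numeric(out_ch)
  l$frozen <- frozen
  l
}

#' Create a fully-connected layer
#' @param in_dim,out_dim input/output dimension.
#' @param frozen if TRUE the optimiser never updates this layer.
#' @keywords internal
#' @export
nn_dense <- function(in_dim, out_dim, frozen = FALSE) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"
  l$W <- matrix(stats::rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)),
                in_dim, out_dim)
  l$b <- numeric(out_dim)
  l$frozen <- frozen
  l
}

#' @keywords internal
#' @export
nn_relu <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "relu"; l
}

#' @keywords internal
#' @export
nn_tanh <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "tanh"; l
}

#' 2x2 average pooling (halves each spatial dimension)
#' @keywords internal
#' @export
nn_avgpool <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "avgpool"; l
}

#' Global average pooling over each channel
#' @keywords internal
#' @export
nn_gap <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "gap"; l
}

#' Assemble layers into a network
#' @param layers list of layer environments, applied in order.
#' @param input_shape integer c(H, W, C) of the expected input.
#' @return a network environment.
#' @keywords internal
#' @export
nn_network <- function(layers, input_shape) {
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$input_shape <- as.integer(input_shape)
  net
}

# im2col for stride-1 same convolution: returns (H*W) x (k*k*C) matrix whose
# row r collects the kxk neighbourhood of output pixel r across channels.
# Column order (di, dj, c) must match the weight-matrix row order in nn_conv.
im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  out <- matrix(0, H * W, k * k * C)
  col <- 1L
  for (c in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    out[, col] <- xp[di + seq_len(H), dj + seq_len(W), c]
    col <- col + 1L
  }
  out
}

# Adjoint of im2col: scatter-add columns back into an H x W x C array.
col2im <- function(cols, H, W, C, k) {
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C))
  col <- 1L
  for (c in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    xp[di + seq_len(H), dj + seq_len(W), c] <-
      xp[di + seq_len(H), dj + seq_len(W), c] + cols[, col]
    col <- col + 1L
  }
  xp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

layer_forward <- function(l, x) {
  switch(l$type,
    conv = {
      d <- dim(x)
      xcol <- im2col(x, l$k)
      y <- xcol %*% l$W
      y <- sweep(y, 2L, l$b, "+")
      list(out = array(y, c(d[1], d[2], l$out_ch)),
           cache = list(xcol = xcol, dim = d))
    },
    dense = {
      xv <- as.numeric(x)
      list(out = drop(crossprod(l$W, xv)) + l$b, cache = list(x = xv))
    },
    relu = {
      y <- x; y[y < 0] <- 0
      list(out = y, cache = list(mask = x > 0))
    },
    tanh = {
      y <- tanh(x)
      list(out = y, cache = list(y = y))
    },
    avgpool = {
      d <- dim(x); H <- d[1]; W <- d[2]
      i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
      j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
      y <- (x[i1, j1, , drop = FALSE] + x[i2, j1, , drop = FALSE] +
            x[i1, j2, , drop = FALSE] + x[i2, j2, , drop = FALSE]) / 4
      list(out = y, cache = list(dim = d))
    },
    gap = {
      d <- dim(x)
      list(out = apply(x, 3L, mean), cache = list(dim = d))
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, cache, dy, accumulate = TRUE) {
  switch(l$type,
    conv = {
      d <- cache$dim
      dym <- matrix(dy, d[1] * d[2], l$out_ch)
      if (accumulate && !isTRUE(l$frozen)) {
        l$gW <- l$gW + crossprod(cache$xcol, dym)
        l$gb <- l$gb + colSums(dym)
      }
      dxcol <- dym %*% t(l$W)
      col2im(dxcol, d[1], d[2], d[3], l$k)
    },
    dense = {
      if (accumulate && !isTRUE(l$frozen)) {
        l$gW <- l$gW + outer(cache$x, dy)
        l$gb <- l$gb + dy
      }
      drop(l$W %*% dy)
    },
    relu = dy * cache$mask,
    tanh = dy * (1 - cache$y^2),
    avgpool = {
      d <- cache$dim
      dx <- array(0, d)
      i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
      j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
      q <- dy / 4
      dx[i1, j1, ] <- q; dx[i2, j1, ] <- q
      dx[i1, j2, ] <- q; dx[i2, j2, ] <- q
      dx
    },
    gap = {
      d <- cache$dim
      array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), d)
    },
    stop("unknown layer type: ", l$type)
  )
}

#' Forward pass through a network
#' @param net network environment.
#' @param x input array matching `net$input_shape` (a matrix is promoted to
#'   a single-channel array).
#' @return list(out, caches); `out` is the last layer's output.
#' @keywords internal
#' @export
nn_forward <- function(net, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    f <- layer_forward(net$layers[[i]], x)
    x <- f$out
    caches[[i]] <- f$cache
  }
  list(out = x, caches = caches)
}

#' Backward pass; accumulates parameter gradients, returns input gradient
#' @param net network environment (after `nn_zero_grad` for a fresh batch).
#' @param caches the caches returned by [nn_forward()].
#' @param dy gradient of the loss w.r.t. the network output.
#' @param accumulate accumulate parameter gradients (FALSE for pure
#'   input-gradient queries, e.g. attribution).
#' @return gradient of the loss w.r.t. the network input, same shape as x.
#' @keywords internal
#' @export
nn_backward <- function(net, caches, dy, accumulate = TRUE) {
  for (i in rev(seq_along(net$layers))) {
    dy <- layer_backward(net$layers[[i]], caches[[i]], dy, accumulate)
  }
  dy
}

#' Zero all accumulated parameter gradients
#' @keywords internal
#' @export
nn_zero_grad <- function(net) {
  for (l in net$layers) {
    if (!is.null(l$W)) {
      l$gW <- l$W * 0
      l$gb <- l$b * 0
    }
  }
  invisible(net)
}

#' SGD with momentum and weight decay (PyTorch convention)
#'
#' v <- momentum * v + g + wd * W;  W <- W - lr * v. Frozen layers are
#' skipped. Gradients are assumed already scaled (e.g. mean over the batch).
#' @keywords internal
nn_sgd_step <- function(net, lr, momentum = 0.9, weight_decay = 0) {
  for (l in net$layers) {
    if (is.null(l$W) || isTRUE(l$frozen)) next
    if (is.null(l$vW)) { l$vW <- l$W * 0; l$vb <- l$b * 0 }
    l$vW <- momentum * l$vW + l$gW + weight_decay * l$W
    l$vb <- momentum * l$vb + l$gb
    l$W <- l$W - lr * l$vW
    l$b <- l$b - lr * l$vb
  }
  invisible(net)
}

#' Adam update (used for adversarial training)
#'
#' Per-parameter moment rescaling keeps sparse, spatially concentrated
#' gradients (a marker-sized region among hundreds of patches) from being
#' drowned by averaging. beta1 = 0.5 as is conventional for adversarial
#' nets. Step counts are kept per layer.
#' @keywords internal
nn_adam_step <- function(net, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (l in net$layers) {
    if (is.null(l$W) || isTRUE(l$frozen)) next
    if (is.null(l$adam_t)) {
      l$adam_t <- 0L
      l$mW <- l$W * 0; l$vW2 <- l$W * 0
      l$mb <- l$b * 0; l$vb2 <- l$b * 0
    }
    l$adam_t <- l$adam_t + 1L
    c1 <- 1 - beta1^l$adam_t; c2 <- 1 - beta2^l$adam_t
    l$mW <- beta1 * l$mW + (1 - beta1) * l$gW
    l$vW2 <- beta2 * l$vW2 + (1 - beta2) * l$gW^2
    l$W <- l$W - lr * (l$mW / c1) / (sqrt(l$vW2 / c2) + eps)
    l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
    l$vb2 <- beta2 * l$vb2 + (1 - beta2) * l$gb^2
    l$b <- l$b - lr * (l$mb / c1) / (sqrt(l$vb2 / c2) + eps)
  }
  invisible(net)
}

#' Deep-copy a network's parameters (for best-epoch snapshots)
#' @keywords internal
nn_get_params <- function(net) {
  lapply(net$layers, function(l) if (is.null(l$W)) NULL else list(W = l$W, b = l$b))
}

#' Restore parameters captured by [nn_get_params()]
#' @keywords internal
nn_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    if (!is.null(params[[i]])) {
      net$layers[[i]]$W <- params[[i]]$W
      net$layers[[i]]$b <- params[[i]]$b
    }
  }
  invisible(net)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
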