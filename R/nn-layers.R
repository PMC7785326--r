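# Minimal explicit-backprop layer framework. Activations are arrays with
# dims (H, W, C, N). Each layer is an environment exposing forward(x,
# training), backward(dy) (after a forward on the same input) and a list of
# parameter environments. A parameter env carries $v (value), $g (gradient
# accumulator), Adam state, an `arc` tag ("encoder"/"decoder") used for
# phase-1 freezing, and an `lr_group` index for discriminative learning
# rates. No deep-learning framework exists in this R environment, so the
# network, its gradients and its optimiser are implemented here.

new_param <- function(value, arc = "decoder", lr_group = 1L) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- array(0, dim = dim(value) %||% length(value))
  p$m <- NULL; p$s <- NULL          # Adam moments, allocated on first step
  p$arc <- arc
  p$lr_group <- lr_group
  p
}

zero_grads <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}

# He-normal initialised 2-D convolution.
nn_conv <- function(cin, cout, k = 3, stride = 1, pad = (k - 1) %/% 2,
                    arc = "decoder", lr_group = 1L) {
  l <- new.env(parent = emptyenv())
  sd <- sqrt(2 / (k * k * cin))
  l$w <- new_param(array(stats::rnorm(k * k * cin * cout, 0, sd),
                         dim = c(k, k, cin, cout)), arc, lr_group)
  l$b <- new_param(numeric(cout), arc, lr_group)
  l$stride <- stride; l$pad <- pad
  l$forward <- function(x, training = TRUE) {
    if (training) l$x <- x
    .conv2d_forward(x, l$w$v, l$b$v, l$stride, l$pad)
  }
  l$backward <- function(dy) {
    gr <- .conv2d_backward(l$x, l$w$v, dy, l$stride, l$pad)
    l$w$g <- l$w$g + gr$dw
    l$b$g <- l$b$g + gr$db
    gr$dx
  }
  l$params <- list(l$w, l$b)
  l
}

# Batch normalisation over (H, W, N) per channel, with running statistics
# for inference mode. The heavy lifting is in C++ (.bn_forward/.bn_backward).
nn_bn <- function(c, momentum = 0.1, eps = 1e-5, arc = "decoder",
                  lr_group = 1L) {
  l <- new.env(parent = emptyenv())
  l$gamma <- new_param(rep(1, c), arc, lr_group)
  l$beta <- new_param(rep(0, c), arc, lr_group)
  l$run_mean <- rep(0, c); l$run_var <- rep(1, c)
  l$eps <- eps; l$momentum <- momentum
  l$forward <- function(x, training = TRUE) {
    res <- .bn_forward(x, l$gamma$v, l$beta$v, l$eps, training,
                       l$run_mean, l$run_var)
    if (training) {
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * res$mu
      l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * res$var
      l$cache <- list(xhat = res$xhat, inv = res$inv)
    }
    res$y
  }
  l$backward <- function(dy) {
    res <- .bn_backward(dy, l$cache$xhat, l$cache$inv, l$gamma$v)
    l$beta$g <- l$beta$g + res$dbeta
    l$gamma$g <- l$gamma$g + res$dgamma
    res$dx
  }
  l$params <- list(l$gamma, l$beta)
  l
}

nn_relu <- function() {
  l <- new.env(parent = emptyenv())
  l$forward <- function(x, training = TRUE) {
    if (training) l$mask <- x > 0
    x * (x > 0)
  }
  l$backward <- function(dy) dy * l$mask
  l$params <- list()
  l
}

nn_maxpool <- function(k = 2, stride = k, pad = 0) {
  l <- new.env(parent = emptyenv())
  l$forward <- function(x, training = TRUE) {
    res <- .maxpool_forward(x, k, stride, pad)
    if (training) { l$argmax <- res$argmax; l$x_dim <- dim(x) }
    res$y
  }
  l$backward <- function(dy) .maxpool_backward(dy, l$argmax, l$x_dim)
  l$params <- list()
  l
}

#' Pixel shuffle: sub-pixel channel-to-space rearrangement
#'
#' Rearranges an input with `C * r^2` channels into `C` channels at `r` times
#' the spatial resolution, by pure index permutation (no arithmetic on
#' values): `output[c, r*h + a, r*w + b] = input[c*r^2 + a*r + b, h, w]` in
#' 0-based indexing. This is the upsampling operator of the decoder; it
#' avoids the checkerboard artifacts of transposed convolutions.
#'
#' @param x Array with dims (H, W, C*r^2) or (H, W, C*r^2, N).
#' @param r Integer upscaling factor.
#' @return Array with dims (r*H, r*W, C) or (r*H, r*W, C, N).
#' @export
#' @examples
#' x <- array(1:4, dim = c(1, 1, 4))
#' pixel_shuffle(x, 2)[, , 1]
pixel_shuffle <- function(x, r) {
  r <- as.integer(r)
  if (r < 1) stop_substacks("r must be >= 1", "substacks_invalid_config")
  was_3d <- length(dim(x)) == 3
  if (was_3d) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  if (d[3] %% (r * r) != 0)
    stop_substacks(sprintf("channel count %d not divisible by r^2 = %d",
                           d[3], r * r), "substacks_invalid_config")
  if (r > 1) {
    C <- d[3] %/% (r * r)
    # view channels as (b, a, c): c_in = c*r^2 + a*r + b (b fastest)
    dim(x) <- c(d[1], d[2], r, r, C, d[4])
    x <- aperm(x, c(4, 1, 3, 2, 5, 6))     # -> (a, h, b, w, c, n)
    dim(x) <- c(r * d[1], r * d[2], C, d[4])
  }
  if (was_3d) dim(x) <- dim(x)[1:3]
  x
}

# Adjoint (and inverse) of pixel_shuffle for 4-D arrays.
pixel_unshuffle <- function(y, r) {
  if (r == 1) return(y)
  d <- dim(y)                              # (rH, rW, C, N)
  H <- d[1] %/% r; W <- d[2] %/% r; C <- d[3]
  dim(y) <- c(r, H, r, W, C, d[4])
  y <- aperm(y, c(2, 4, 3, 1, 5, 6))       # -> (h, w, b, a, c, n)
  dim(y) <- c(H, W, r * r * C, d[4])
  y
}

nn_shuffle <- function(r) {
  l <- new.env(parent = emptyenv())
  l$forward <- function(x, training = TRUE) pixel_shuffle(x, r)
  l$backward <- function(dy) pixel_unshuffle(dy, r)
  l$params <- list()
  l
}

# Sequential container.
nn_seq <- function(...) {
  l <- new.env(parent = emptyenv())
  l$layers <- list(...)
  l$forward <- function(x, training = TRUE) {
    for (sub in l$layers) x <- sub$forward(x, training)
    x
  }
  l$backward <- function(dy) {
    for (sub in rev(l$layers)) dy <- sub$backward(dy)
    dy
  }
  l$params <- unlist(lapply(l$layers, function(s) s$params),
                     recursive = FALSE) %||% list()
  l
}

# ResNet basic block: conv-bn-relu-conv-bn plus (projected) identity, relu.
nn_basic_block <- function(cin, cout, stride = 1, arc = "encoder",
                           lr_group = 1L) {
  l <- new.env(parent = emptyenv())
  l$conv1 <- nn_conv(cin, cout, 3, stride, 1, arc, lr_group)
  l$bn1 <- nn_bn(cout, arc = arc, lr_group = lr_group)
  l$relu1 <- nn_relu()
  l$conv2 <- nn_conv(cout, cout, 3, 1, 1, arc, lr_group)
  l$bn2 <- nn_bn(cout, arc = arc, lr_group = lr_group)
  l$project <- stride != 1 || cin != cout
  if (l$project) {
    l$convp <- nn_conv(cin, cout, 1, stride, 0, arc, lr_group)
    l$bnp <- nn_bn(cout, arc = arc, lr_group = lr_group)
  }
  l$forward <- function(x, training = TRUE) {
    main <- l$bn2$forward(l$conv2$forward(
      l$relu1$forward(l$bn1$forward(l$conv1$forward(x, training), training),
                      training), training), training)
    short <- if (l$project)
      l$bnp$forward(l$convp$forward(x, training), training) else x
    y <- main + short
    if (training) l$out_mask <- y > 0
    y * (y > 0)
  }
  l$backward <- function(dy) {
    dy <- dy * l$out_mask
    dmain <- l$conv1$backward(l$bn1$backward(l$relu1$backward(
      l$conv2$backward(l$bn2$backward(dy)))))
    dshort <- if (l$project) l$convp$backward(l$bnp$backward(dy)) else dy
    dmain + dshort
  }
  l$params <- c(l$conv1$params, l$bn1$params, l$conv2$params, l$bn2$params,
                if (l$project) c(l$convp$params, l$bnp$params))
  l
}

# Channel-wise concatenation (skip connections).
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(d, c1) {
  list(first = seq_len(c1), second = c1 + seq_len(d - c1))
}

# ---- Adam -------------------------------------------------------------------

adam_step <- function(params, lr_mults, lr, iter, beta1 = 0.9, beta2 = 0.99,
                      eps = 1e-8, wd = 0, skip_arc = NULL) {
  bc1 <- 1 - beta1^iter
  bc2 <- 1 - beta2^iter
  for (p in params) {
    if (!is.null(skip_arc) && p$arc %in% skip_arc) next
    if (is.null(p$m)) { p$m <- p$g * 0; p$s <- p$g * 0 }
    g <- p$g
    if (wd > 0) g <- g + wd * p$v
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$s <- beta2 * p$s + (1 - beta2) * g^2
    step_lr <- lr * lr_mults[p$lr_group]
    p$v <- p$v - step_lr * (p$m / bc1) / (sqrt(p$s / bc2) + eps)
  }
  invisible(NULL)
}
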