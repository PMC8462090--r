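# Minimal neural-network engine with manual backpropagation.
#
# Tensors are column-major R arrays of shape (d1, d2, d3, C, N): three
# spatial/spectral dimensions, a channel dimension and a sample dimension.
# A 1-D spectral network uses d1 = d2 = 1.  Layers are environments so that
# parameter updates and cached activations mutate in place; the convolution
# itself is compiled (see src/conv.cpp).

nn_new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

# He-normal initialization, the standard choice for ReLU networks
nn_he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

nn_conv <- function(in_ch, out_ch, kern, stride = c(1L, 1L, 1L),
                    pad = (as.integer(kern) - 1L) %/% 2L) {
  kern <- as.integer(kern)
  K <- prod(kern) * in_ch
  nn_new_layer("conv",
               in_ch = in_ch, out_ch = out_ch, kern = kern,
               stride = as.integer(stride), pad = as.integer(pad),
               W = nn_he_init(K, out_ch, K), b = numeric(out_ch))
}

nn_bn <- function(n_channels, momentum = 0.9, eps = 1e-5) {
  nn_new_layer("bn",
               C = n_channels, momentum = momentum, eps = eps,
               gamma = rep(1, n_channels), beta = numeric(n_channels),
               running_mean = numeric(n_channels),
               running_var = rep(1, n_channels))
}

nn_relu <- function() nn_new_layer("relu")

# Fused pre-activation BN + ReLU (parameters live in the bn slots)
nn_bnrelu <- function(n_channels, momentum = 0.9, eps = 1e-5) {
  nn_new_layer("bnrelu",
               C = n_channels, momentum = momentum, eps = eps,
               gamma = rep(1, n_channels), beta = numeric(n_channels),
               running_mean = numeric(n_channels),
               running_var = rep(1, n_channels))
}

nn_dropout <- function(p) nn_new_layer("dropout", p = p)

nn_gap <- function() nn_new_layer("gap")

nn_dense <- function(n_in, n_out) {
  nn_new_layer("dense", n_in = n_in, n_out = n_out,
               W = nn_he_init(n_out, n_in, n_in), b = numeric(n_out))
}

# Pre-activation bottleneck residual block: BN-ReLU-conv(1) compressing to
# `mid` channels, BN-ReLU-conv(k, stride) at the bottleneck width, then
# BN-ReLU-conv(1) expanding to `width`.  The shortcut is the identity unless
# the channel count or resolution changes, in which case a strided 1x1(x1)
# convolution projects the input.
nn_bottleneck <- function(in_ch, width, mid, stride, ndim, block_kernel = 3L) {
  if (ndim == 1) {
    k <- c(1L, 1L, block_kernel)
    st <- c(1L, 1L, as.integer(stride))
  } else {
    k <- rep(as.integer(block_kernel), 3L)
    st <- rep(as.integer(stride), 3L)
  }
  main <- list(
    nn_bnrelu(in_ch), nn_conv(in_ch, mid, c(1L, 1L, 1L)),
    nn_bnrelu(mid), nn_conv(mid, mid, k, stride = st),
    nn_bnrelu(mid), nn_conv(mid, width, c(1L, 1L, 1L)))
  shortcut <- if (in_ch != width || any(st != 1L)) {
    nn_conv(in_ch, width, c(1L, 1L, 1L), stride = st)
  }
  nn_new_layer("bottleneck", main = main, shortcut = shortcut)
}

# Reusable buffer attached to a layer/network environment, keyed by length.
# The hot path writes into these through the in-place C++ kernels, so large
# tensors are allocated once per (layer, shape) rather than per iteration.
nn_buf <- function(l, name, len, dims = NULL) {
  key <- paste0(name, "_", len)
  b <- l[[key]]
  if (is.null(b)) {
    b <- numeric(len)
    if (!is.null(dims)) dim(b) <- as.integer(dims)
    l[[key]] <- b
  }
  b
}

conv_out_dims <- function(xdim, kern, stride, pad, out_ch) {
  o <- (xdim[1:3] + 2L * pad - kern) %/% stride + 1L
  c(o, out_ch, xdim[5])
}

nn_forward_layer <- function(l, x, training) {
  switch(l$type,
    conv = {
      l$x <- x
      l$xdim <- dim(x)
      l$float_mode <- training
      od <- conv_out_dims(dim(x), l$kern, l$stride, l$pad, l$out_ch)
      y <- nn_buf(l, "fy", prod(od), od)
      conv_fwd_ip(x, dim(x), l$W, l$b, l$kern, l$stride, l$pad, training, y)
      y
    },
    bn = nn_bn_forward(l, x, training),
    bnrelu = {
      d <- dim(x)
      y <- nn_buf(l, "fy", length(x), d)
      xh <- nn_buf(l, "fxh", length(x))
      r <- bnrelu_fwd_ip(x, prod(d[1:3]), d[4], d[5], l$gamma, l$beta,
                         l$running_mean, l$running_var, l$momentum, l$eps,
                         training, y, xh)
      l$running_mean <- r$running_mean
      l$running_var <- r$running_var
      l$xhat <- xh
      l$y <- y
      l$invstd <- r$invstd
      l$dims <- d
      l$train_mode <- training
      y
    },
    relu = {
      l$y <- relu_fwd(x)
      l$y
    },
    dropout = {
      if (training && l$p > 0) {
        l$mask <- (stats::runif(length(x)) >= l$p) / (1 - l$p)
        x * l$mask
      } else {
        l$mask <- NULL
        x
      }
    },
    gap = {
      d <- dim(x)
      l$dims <- d
      S <- prod(d[1:3])
      matrix(colMeans(matrix(x, nrow = S)), d[4], d[5])
    },
    dense = {
      l$x <- x
      l$W %*% x + l$b
    },
    bottleneck = {
      h <- x
      for (sl in l$main) h <- nn_forward_layer(sl, h, training)
      sc <- if (is.null(l$shortcut)) x else
        nn_forward_layer(l$shortcut, x, training)
      # h is the expand convolution's own output buffer; accumulate the
      # shortcut into it in place (the convolution's backward pass never
      # reads its own output)
      add_ip(h, sc)
      h
    },
    stop("unknown layer type: ", l$type))
}

nn_backward_layer <- function(l, dy, need_dx = TRUE) {
  switch(l$type,
    conv = {
      dW <- nn_buf(l, "gW", length(l$W), dim(l$W))
      db <- nn_buf(l, "gb", length(l$b))
      dx <- if (need_dx) nn_buf(l, "bdx", prod(l$xdim), l$xdim) else
        numeric(0)
      conv_bwd_ip(l$x, l$xdim, l$W, dy, l$kern, l$stride, l$pad, need_dx,
                  isTRUE(l$float_mode), dx, dW, db)
      l$g_W <- dW
      l$g_b <- db
      if (need_dx) dx else NULL
    },
    bn = nn_bn_backward(l, dy),
    bnrelu = {
      d <- l$dims
      dx <- nn_buf(l, "bdx", length(dy), d)
      r <- bnrelu_bwd_ip(dy, l$xhat, l$y, prod(d[1:3]), d[4], d[5],
                         l$gamma, l$invstd, isTRUE(l$train_mode), dx)
      l$g_gamma <- r$g_gamma
      l$g_beta <- r$g_beta
      dx
    },
    relu = relu_bwd(dy, l$y),
    dropout = if (is.null(l$mask)) dy else dy * l$mask,
    gap = {
      S <- prod(l$dims[1:3])
      array(rep(as.numeric(dy), each = S) / S, l$dims)
    },
    dense = {
      l$g_W <- dy %*% t(l$x)
      l$g_b <- rowSums(dy)
      t(l$W) %*% dy
    },
    bottleneck = {
      dsc <- if (is.null(l$shortcut)) dy else
        nn_backward_layer(l$shortcut, dy)
      dh <- dy
      for (sl in rev(l$main)) dh <- nn_backward_layer(sl, dh)
      add_ip(dh, dsc)
      dh
    },
    stop("unknown layer type: ", l$type))
}

nn_bn_forward <- function(l, x, training) {
  d <- dim(x)
  r <- bn_fwd(x, prod(d[1:3]), d[4], d[5], l$gamma, l$beta,
              l$running_mean, l$running_var, l$momentum, l$eps, training)
  l$running_mean <- r$running_mean
  l$running_var <- r$running_var
  l$xhat <- r$xhat
  l$invstd <- r$invstd
  l$dims <- d
  l$train_mode <- training
  r$y
}

nn_bn_backward <- function(l, dy) {
  d <- l$dims
  r <- bn_bwd(dy, l$xhat, prod(d[1:3]), d[4], d[5], l$gamma, l$invstd,
              isTRUE(l$train_mode))
  l$g_gamma <- r$g_gamma
  l$g_beta <- r$g_beta
  r$dx
}

# --- network container ------------------------------------------------------

nn_network <- function(layers) {
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$flat <- nn_flatten(layers)
  net$t <- 0L
  net
}

nn_flatten <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "bottleneck") {
      out <- c(out, nn_flatten(l$main))
      if (!is.null(l$shortcut)) out <- c(out, list(l$shortcut))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}

nn_param_names <- function(l) {
  switch(l$type,
         conv = c("W", "b"),
         dense = c("W", "b"),
         bn = c("gamma", "beta"),
         bnrelu = c("gamma", "beta"),
         character(0))
}

nn_state_names <- function(l) {
  switch(l$type,
         conv = c("W", "b"),
         dense = c("W", "b"),
         bn = c("gamma", "beta", "running_mean", "running_var"),
         bnrelu = c("gamma", "beta", "running_mean", "running_var"),
         character(0))
}

nn_forward <- function(net, x, training = FALSE) {
  for (l in net$layers) x <- nn_forward_layer(l, x, training)
  x
}

nn_backward <- function(net, dy, need_input_grad = TRUE) {
  nl <- length(net$layers)
  for (i in rev(seq_len(nl))) {
    dy <- nn_backward_layer(net$layers[[i]], dy,
                            need_dx = i > 1L || need_input_grad)
  }
  dy
}

nn_adam_step <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$t <- net$t + 1L
  bc1 <- 1 - beta1^net$t
  bc2 <- 1 - beta2^net$t
  for (l in net$flat) {
    for (p in nn_param_names(l)) {
      g <- l[[paste0("g_", p)]]
      if (is.null(g)) next
      ms <- paste0("m_", p)
      vs <- paste0("v_", p)
      if (is.null(l[[ms]])) {
        l[[ms]] <- g * 0
        l[[vs]] <- g * 0
      }
      l[[ms]] <- beta1 * l[[ms]] + (1 - beta1) * g
      l[[vs]] <- beta2 * l[[vs]] + (1 - beta2) * (g * g)
      l[[p]] <- l[[p]] - lr * (l[[ms]] / bc1) / (sqrt(l[[vs]] / bc2) + eps)
    }
  }
  invisible(net)
}

nn_get_state <- function(net) {
  lapply(net$flat, function(l) {
    nms <- nn_state_names(l)
    stats::setNames(lapply(nms, function(p) l[[p]]), nms)
  })
}

nn_set_state <- function(net, state) {
  stopifnot(length(state) == length(net$flat))
  for (i in seq_along(state)) {
    for (p in names(state[[i]])) net$flat[[i]][[p]] <- state[[i]][[p]]
  }
  invisible(net)
}

nn_n_params <- function(net) {
  sum(vapply(net$flat, function(l) {
    sum(vapply(nn_param_names(l), function(p) length(l[[p]]), 0))
  }, 0))
}

# Shapes of all trainable parameters, in network order.  Used to check that
# classification and regression variants share an identical trunk.
nn_param_shapes <- function(net) {
  out <- list()
  for (l in net$flat) {
    for (p in nn_param_names(l)) {
      out[[length(out) + 1L]] <- c(layer = l$type, param = p,
                                   dims = paste(dim(l[[p]]) %||% length(l[[p]]),
                                                collapse = "x"))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- losses -----------------------------------------------------------------

nn_softmax <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

nn_loss_softmax_ce <- function(logits, y) {
  N <- ncol(logits)
  p <- nn_softmax(logits)
  ii <- cbind(y, seq_len(N))
  loss <- -mean(log(pmax(p[ii], 1e-300)))
  grad <- p
  grad[ii] <- grad[ii] - 1
  list(loss = loss, grad = grad / N, prob = p)
}

nn_loss_l2 <- function(yhat, y) {
  r <- as.numeric(yhat) - y
  list(loss = mean(r^2), grad = matrix(2 * r / length(r), nrow = 1),
       pred = as.numeric(yhat))
}

# Slice samples (last dimension) out of a batch tensor
nn_slice <- function(x, idx) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 5) {
    x[, , , , idx, drop = FALSE]
  } else if (nd == 2) {
    x[, idx, drop = FALSE]
  } else {
    stop("unsupported tensor rank")
  }
}
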