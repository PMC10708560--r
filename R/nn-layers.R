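# Minimal reverse-mode layer framework for the temporal networks.
#
# Sequence tensors are numeric arrays of dim (time, channels, batch);
# after flatten/pooling, dense layers operate on (batch, features)
# matrices. Each leaf layer implements a forward pass returning
# list(node, y, cache) and a backward pass returning list(dx, grads),
# with `grads` named like the layer's `params`. Containers ("seq",
# "residual") recurse. Heavy kernels (convolution, LSTM, max-pooling)
# live in src/nn_ops.cpp; everything else is plain R linear algebra.

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

nn_conv1d <- function(in_ch, out_ch, kernel, dilation = 1L,
                      padding = c("valid", "causal")) {
  padding <- match.arg(padding)
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       dilation = as.integer(dilation), padding = padding,
       params = list(W = glorot(kernel * in_ch, kernel * out_ch,
                                c(kernel, in_ch, out_ch)),
                     b = numeric(out_ch)))
}

nn_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = glorot(in_dim, out_dim, c(in_dim, out_dim)),
                     b = numeric(out_dim)))
}

nn_lstm_bi <- function(in_ch, units) {
  lim <- 1 / sqrt(units)
  init <- function(d) array(stats::runif(prod(d), -lim, lim), d)
  bias <- function() {
    b <- numeric(4 * units)
    b[(units + 1):(2 * units)] <- 1  # forget-gate bias starts open
    b
  }
  list(type = "lstm_bi", in_ch = in_ch, units = units,
       params = list(f_Wx = init(c(in_ch, 4 * units)),
                     f_Wh = init(c(units, 4 * units)), f_b = bias(),
                     b_Wx = init(c(in_ch, 4 * units)),
                     b_Wh = init(c(units, 4 * units)), b_b = bias()))
}

nn_batchnorm <- function(channels, momentum = 0.9, eps = 1e-3) {
  list(type = "batchnorm", channels = channels, momentum = momentum,
       eps = eps,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       buffers = list(run_mean = numeric(channels),
                      run_var = rep(1, channels)))
}

# fused batch norm + ReLU + dropout (the repeated TCN-block tail);
# numerically identical to the separate layers but one kernel pass
nn_bn_act_drop <- function(channels, rate, momentum = 0.9, eps = 1e-3) {
  list(type = "bn_act_drop", channels = channels, rate = rate,
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       buffers = list(run_mean = numeric(channels),
                      run_var = rep(1, channels)))
}

nn_relu <- function() list(type = "relu", params = NULL)
nn_maxpool <- function(pool) list(type = "maxpool", pool = as.integer(pool),
                                  params = NULL)
nn_gap <- function() list(type = "gap", params = NULL)
nn_flatten <- function() list(type = "flatten", params = NULL)
nn_dropout <- function(rate) list(type = "dropout", rate = rate,
                                  params = NULL)
nn_softmax <- function() list(type = "softmax", params = NULL)

nn_seq <- function(...) list(type = "seq", layers = list(...), params = NULL)

nn_residual <- function(body, skip = NULL)
  list(type = "residual", body = body, skip = skip, params = NULL)

net_forward <- function(node, x, training = FALSE) {
  switch(node$type,
    seq = {
      caches <- vector("list", length(node$layers))
      for (i in seq_along(node$layers)) {
        r <- net_forward(node$layers[[i]], x, training)
        node$layers[[i]] <- r$node
        caches[i] <- list(r$cache)   # keep NULL slots for cache-free layers
        x <- r$y
      }
      list(node = node, y = x, cache = caches)
    },
    residual = {
      b <- net_forward(node$body, x, training)
      node$body <- b$node
      if (is.null(node$skip)) {
        pre <- b$y + x
        s_cache <- NULL
      } else {
        s <- net_forward(node$skip, x, training)
        node$skip <- s$node
        pre <- b$y + s$y
        s_cache <- s$cache
      }
      y <- cpp_relu_fw(pre)
      list(node = node, y = y,
           cache = list(body = b$cache, skip = s_cache, y = y))
    },
    conv1d = {
      y <- cpp_conv1d_fw(x, node$params$W, node$params$b, node$dilation,
                         node$padding == "causal")
      list(node = node, y = y, cache = x)
    },
    dense = {
      y <- x %*% node$params$W
      y <- sweep(y, 2, node$params$b, "+")
      list(node = node, y = y, cache = x)
    },
    lstm_bi = {
      f <- cpp_lstm_fw(x, node$params$f_Wx, node$params$f_Wh,
                       node$params$f_b, FALSE)
      b <- cpp_lstm_fw(x, node$params$b_Wx, node$params$b_Wh,
                       node$params$b_b, TRUE)
      d <- dim(x)
      H <- node$units
      y <- array(0, c(d[1], 2 * H, d[3]))
      y[, 1:H, ] <- f$h
      y[, H + (1:H), ] <- b$h
      list(node = node, y = y, cache = list(x = x, f = f, b = b))
    },
    batchnorm = {
      d <- dim(x)
      n_per_chan <- d[1] * d[3]
      if (training) {
        mu <- as.numeric(cpp_chan_sum(x)) / n_per_chan
        centered <- cpp_chan_affine(x, rep(1, d[2]), -mu)
        va <- as.numeric(cpp_chan_dot(centered, centered)) / n_per_chan
        node$buffers$run_mean <- node$momentum * node$buffers$run_mean +
          (1 - node$momentum) * mu
        node$buffers$run_var <- node$momentum * node$buffers$run_var +
          (1 - node$momentum) * va
      } else {
        mu <- node$buffers$run_mean
        va <- node$buffers$run_var
      }
      inv_sd <- 1 / sqrt(va + node$eps)
      r <- cpp_bn_fw(x, mu, inv_sd, node$params$gamma, node$params$beta)
      list(node = node, y = r$y,
           cache = list(xhat = r$xhat, inv_sd = inv_sd,
                        n_per_chan = n_per_chan, training = training))
    },
    bn_act_drop = {
      d <- dim(x)
      n_per_chan <- d[1] * d[3]
      if (training) {
        mu <- as.numeric(cpp_chan_sum(x)) / n_per_chan
        centered <- cpp_chan_affine(x, rep(1, d[2]), -mu)
        va <- as.numeric(cpp_chan_dot(centered, centered)) / n_per_chan
        node$buffers$run_mean <- node$momentum * node$buffers$run_mean +
          (1 - node$momentum) * mu
        node$buffers$run_var <- node$momentum * node$buffers$run_var +
          (1 - node$momentum) * va
      } else {
        mu <- node$buffers$run_mean
        va <- node$buffers$run_var
      }
      inv_sd <- 1 / sqrt(va + node$eps)
      r <- cpp_bnad_fw(x, node$params$gamma, node$params$beta, mu, inv_sd,
                       node$rate, training)
      list(node = node, y = r$y,
           cache = list(xhat = r$xhat, cmask = r$cmask, inv_sd = inv_sd,
                        training = training))
    },
    relu = {
      if (length(dim(x)) == 3) {
        y <- cpp_relu_fw(x)
        list(node = node, y = y, cache = y)
      } else {
        mask <- x > 0
        list(node = node, y = x * mask, cache = mask)
      }
    },
    maxpool = {
      r <- cpp_maxpool1d_fw(x, node$pool)
      list(node = node, y = r$y, cache = list(idx = r$idx, t_in = dim(x)[1]))
    },
    gap = {
      d <- dim(x)
      cm <- colMeans(matrix(x, nrow = d[1]))       # (C*B)
      list(node = node, y = t(matrix(cm, d[2], d[3])), cache = d)
    },
    flatten = {
      d <- dim(x)
      list(node = node, y = t(matrix(x, nrow = d[1] * d[2])), cache = d)
    },
    dropout = {
      if (training && node$rate > 0) {
        if (length(dim(x)) == 3) {
          r <- cpp_dropout_fw(x, node$rate)
          list(node = node, y = r$y, cache = r$mask)
        } else {
          mask <- (stats::runif(length(x)) >= node$rate) / (1 - node$rate)
          dim(mask) <- dim(x)
          list(node = node, y = x * mask, cache = mask)
        }
      } else {
        list(node = node, y = x, cache = NULL)
      }
    },
    softmax = {
      z <- x - apply(x, 1, max)
      e <- exp(z)
      list(node = node, y = e / rowSums(e), cache = NULL)
    },
    stop("unknown layer type: ", node$type))
}

# Backward pass. For "softmax" the incoming gradient is taken to be the
# gradient w.r.t. the logits (the cross-entropy loss supplies p - y), so
# the layer passes it through unchanged; softmax is never used with any
# other loss in this package.
net_backward <- function(node, cache, dy) {
  switch(node$type,
    seq = {
      grads <- vector("list", length(node$layers))
      for (i in rev(seq_along(node$layers))) {
        r <- net_backward(node$layers[[i]], cache[[i]], dy)
        grads[i] <- list(r$grads)   # keep NULL slots for param-free layers
        dy <- r$dx
      }
      list(dx = dy, grads = grads)
    },
    residual = {
      dpre <- cpp_relu_bw(cache$y, dy)
      b <- net_backward(node$body, cache$body, dpre)
      if (is.null(node$skip)) {
        dx <- b$dx + dpre
        s_grads <- NULL
      } else {
        s <- net_backward(node$skip, cache$skip, dpre)
        dx <- b$dx + s$dx
        s_grads <- s$grads
      }
      list(dx = dx, grads = list(body = b$grads, skip = s_grads))
    },
    conv1d = {
      r <- cpp_conv1d_bw(cache, node$params$W, dy, node$dilation,
                         node$padding == "causal")
      list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    dense = {
      list(dx = dy %*% t(node$params$W),
           grads = list(W = t(cache) %*% dy, b = colSums(dy)))
    },
    lstm_bi = {
      H <- node$units
      f <- cpp_lstm_bw(cache$x, node$params$f_Wx, node$params$f_Wh,
                       dy[, 1:H, , drop = FALSE], cache$f$i, cache$f$f,
                       cache$f$g, cache$f$o, cache$f$c, FALSE)
      b <- cpp_lstm_bw(cache$x, node$params$b_Wx, node$params$b_Wh,
                       dy[, H + (1:H), , drop = FALSE], cache$b$i,
                       cache$b$f, cache$b$g, cache$b$o, cache$b$c, TRUE)
      list(dx = f$dx + b$dx,
           grads = list(f_Wx = f$dWx, f_Wh = f$dWh, f_b = as.numeric(f$db),
                        b_Wx = b$dWx, b_Wh = b$dWh, b_b = as.numeric(b$db)))
    },
    batchnorm = {
      dgamma <- as.numeric(cpp_chan_dot(dy, cache$xhat))
      dbeta <- as.numeric(cpp_chan_sum(dy))
      zero <- numeric(length(dbeta))
      dxhat <- cpp_chan_affine(dy, node$params$gamma, zero)
      if (cache$training) {
        m1 <- as.numeric(cpp_chan_sum(dxhat)) / cache$n_per_chan
        m2 <- as.numeric(cpp_chan_dot(dxhat, cache$xhat)) / cache$n_per_chan
        dx <- cpp_bn_bw_dx(dxhat, cache$xhat, m1, m2, cache$inv_sd)
      } else {
        dx <- cpp_chan_affine(dxhat, cache$inv_sd, zero)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    bn_act_drop = {
      r <- cpp_bnad_bw(dy, cache$xhat, cache$cmask, node$params$gamma,
                       cache$inv_sd, cache$training)
      list(dx = r$dx, grads = list(gamma = as.numeric(r$dgamma),
                                   beta = as.numeric(r$dbeta)))
    },
    relu = {
      if (length(dim(dy)) == 3) list(dx = cpp_relu_bw(cache, dy), grads = NULL)
      else list(dx = dy * cache, grads = NULL)
    },
    maxpool = list(dx = cpp_maxpool1d_bw(cache$idx, dy, cache$t_in),
                   grads = NULL),
    gap = {
      d <- cache
      dx <- array(rep(as.vector(t(dy)) / d[1], each = d[1]), d)
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(t(dy), cache), grads = NULL),
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else if (length(dim(dy)) == 3) list(dx = cpp_mul(dy, cache),
                                          grads = NULL)
      else list(dx = dy * cache, grads = NULL)
    },
    softmax = list(dx = dy, grads = NULL),
    stop("unknown layer type: ", node$type))
}

# --- parameter plumbing -----------------------------------------------

flatten_params <- function(node, path = "net") {
  switch(node$type,
    seq = {
      out <- list()
      for (i in seq_along(node$layers))
        out <- c(out, flatten_params(node$layers[[i]],
                                     paste0(path, ".", i)))
      out
    },
    residual = {
      out <- flatten_params(node$body, paste0(path, ".body"))
      if (!is.null(node$skip))
        out <- c(out, flatten_params(node$skip, paste0(path, ".skip")))
      out
    },
    {
      if (is.null(node$params)) return(list())
      stats::setNames(node$params,
                      paste0(path, "|", names(node$params)))
    })
}

flatten_grads <- function(node, grads, path = "net") {
  switch(node$type,
    seq = {
      out <- list()
      for (i in seq_along(node$layers))
        out <- c(out, flatten_grads(node$layers[[i]], grads[[i]],
                                    paste0(path, ".", i)))
      out
    },
    residual = {
      out <- flatten_grads(node$body, grads$body, paste0(path, ".body"))
      if (!is.null(node$skip))
        out <- c(out, flatten_grads(node$skip, grads$skip,
                                    paste0(path, ".skip")))
      out
    },
    {
      if (is.null(node$params)) return(list())
      stats::setNames(grads, paste0(path, "|", names(node$params)))
    })
}

assign_params <- function(node, flat, path = "net") {
  switch(node$type,
    seq = {
      for (i in seq_along(node$layers))
        node$layers[[i]] <- assign_params(node$layers[[i]], flat,
                                          paste0(path, ".", i))
      node
    },
    residual = {
      node$body <- assign_params(node$body, flat, paste0(path, ".body"))
      if (!is.null(node$skip))
        node$skip <- assign_params(node$skip, flat, paste0(path, ".skip"))
      node
    },
    {
      if (!is.null(node$params)) {
        keys <- paste0(path, "|", names(node$params))
        for (j in seq_along(keys)) {
          val <- flat[[keys[j]]]
          dim(val) <- dim(node$params[[j]])
          node$params[[j]] <- val
        }
      }
      node
    })
}

count_buffer_params <- function(node) {
  switch(node$type,
    seq = sum(vapply(node$layers, count_buffer_params, numeric(1))),
    residual = count_buffer_params(node$body) +
      (if (is.null(node$skip)) 0 else count_buffer_params(node$skip)),
    if (is.null(node$buffers)) 0 else sum(lengths(node$buffers)))
}
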