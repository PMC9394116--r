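# Minimal 1-D CNN engine: layer primitives with forward/backward passes over
# BLAS matrix products, enough to express the gated-attention base classifier
# and the fusion architectures, and to train them with minibatch SGD.
#
# Conventions: dense-stage activations are (batch x features) matrices;
# conv-stage activations are (batch*length x channels) matrices with rows
# ordered sample-major (row = (i-1)*len + t), carrying attrs n/len. Losses
# are means over the batch, so gradients returned by the loss are already
# 1/N-scaled.

he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

## ---- layer constructors -------------------------------------------------

layer_attention <- function(d, h) {
  list(type = "attention",
       W1 = he_init(h, d) * 0.1,  # (h x d): gate pre-activation is H %*% W1
       W2 = he_init(d, h) * 0.1,
       b1 = numeric(h),
       b2 = rep(1, d))            # identity-like gate at init keeps signal flowing
}

layer_conv <- function(c_in, c_out) {
  list(type = "conv", W = he_init(3 * c_in, c_out), b = numeric(c_out),
       c_in = c_in, c_out = c_out)
}

layer_dense <- function(p, q) {
  list(type = "dense", W = he_init(p, q), b = numeric(q))
}

layer_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.9, eps = 1e-5)
}

layer_relu <- function() list(type = "relu")
layer_maxpool <- function() list(type = "maxpool")
layer_to_conv <- function() list(type = "to_conv")
layer_flatten <- function() list(type = "flatten")

## ---- forward ------------------------------------------------------------

# returns list(out, cache, layer); `layer` is returned because batch norm
# updates its running statistics during training
layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    attention = {
      h_pre <- sweep(x %*% layer$W2, 2, layer$b1, "+")
      h <- h_pre * (h_pre > 0)
      g_pre <- sweep(h %*% layer$W1, 2, layer$b2, "+")
      g <- g_pre * (g_pre > 0)
      list(out = g * x, cache = list(x = x, h = h, g = g), layer = layer)
    },
    to_conv = {
      n <- nrow(x); len <- ncol(x)
      out <- matrix(as.vector(t(x)), ncol = 1)
      attr(out, "n") <- n; attr(out, "len") <- len
      list(out = out, cache = list(n = n, len = len), layer = layer)
    },
    conv = {
      n <- attr(x, "n"); len <- attr(x, "len")
      idx <- conv_shift_index(n, len)
      zrow <- nrow(x) + 1L
      xz <- rbind(x, 0)
      xcol <- cbind(xz[idx$prev, , drop = FALSE], x, xz[idx$nxt, , drop = FALSE])
      out <- sweep(xcol %*% layer$W, 2, layer$b, "+")
      attr(out, "n") <- n; attr(out, "len") <- len
      list(out = out, cache = list(xcol = xcol, n = n, len = len, idx = idx),
           layer = layer)
    },
    relu = {
      mask <- x > 0
      out <- x * mask
      attr(out, "n") <- attr(x, "n"); attr(out, "len") <- attr(x, "len")
      list(out = out, cache = list(mask = mask), layer = layer)
    },
    maxpool = {
      n <- attr(x, "n"); len <- attr(x, "len")
      lo <- len %/% 2L
      base <- rep((seq_len(n) - 1L) * len, each = lo)
      odd <- base + rep(seq(1L, by = 2L, length.out = lo), times = n)
      xo <- x[odd, , drop = FALSE]
      xe <- x[odd + 1L, , drop = FALSE]
      takes_odd <- xo >= xe
      out <- xo * takes_odd + xe * (!takes_odd)
      attr(out, "n") <- n; attr(out, "len") <- lo
      list(out = out,
           cache = list(odd = odd, takes_odd = takes_odd, n = n, len = len),
           layer = layer)
    },
    bn = {
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc * xc)
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
        xc <- sweep(x, 2, mu)
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2, inv_sd, "*")
      out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      attr(out, "n") <- attr(x, "n"); attr(out, "len") <- attr(x, "len")
      list(out = out,
           cache = list(xhat = xhat, inv_sd = inv_sd, training = training),
           layer = layer)
    },
    flatten = {
      n <- attr(x, "n"); len <- attr(x, "len"); ch <- ncol(x)
      out <- matrix(aperm(array(x, c(len, n, ch)), c(2, 1, 3)), n, len * ch)
      list(out = out, cache = list(n = n, len = len, ch = ch), layer = layer)
    },
    dense = {
      list(out = sweep(x %*% layer$W, 2, layer$b, "+"),
           cache = list(x = x), layer = layer)
    },
    stop("unknown layer type ", layer$type)
  )
}

conv_shift_index <- function(n, len) {
  zrow <- n * len + 1L
  r <- seq_len(n * len)
  t_pos <- ((r - 1L) %% len) + 1L
  prev <- ifelse(t_pos == 1L, zrow, r - 1L)
  nxt <- ifelse(t_pos == len, zrow, r + 1L)
  list(prev = prev, nxt = nxt)
}

## ---- backward -----------------------------------------------------------

# returns list(dx, grads); grads is a named list matching the layer's
# trainable parameters (NULL for parameterless layers)
layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    attention = {
      x <- cache$x; h <- cache$h; g <- cache$g
      dg <- dout * x
      dx <- dout * g
      du2 <- dg * (g > 0)
      dW1 <- crossprod(h, du2)     # (h x d), matching storage
      db2 <- colSums(du2)
      dh <- tcrossprod(du2, layer$W1)  # (n x h)
      du1 <- dh * (h > 0)
      dW2 <- crossprod(x, du1)     # (d x h)
      db1 <- colSums(du1)
      dx <- dx + tcrossprod(du1, layer$W2)
      list(dx = dx, grads = list(W1 = dW1, W2 = dW2, b1 = db1, b2 = db2))
    },
    to_conv = {
      dx <- matrix(dout, cache$len, cache$n)  # (n*len x 1) -> len x n
      list(dx = t(dx), grads = NULL)
    },
    conv = {
      c_in <- layer$c_in
      dW <- crossprod(cache$xcol, dout)
      db <- colSums(dout)
      dxcol <- tcrossprod(dout, layer$W)
      dx <- dxcol[, c_in + seq_len(c_in), drop = FALSE]
      nl <- cache$n * cache$len
      # left block read x[t-1]: its gradient flows to rows prev
      pv <- cache$idx$prev
      ok <- pv <= nl
      dx[pv[ok], ] <- dx[pv[ok], , drop = FALSE] +
        dxcol[ok, seq_len(c_in), drop = FALSE]
      nx <- cache$idx$nxt
      ok2 <- nx <= nl
      dx[nx[ok2], ] <- dx[nx[ok2], , drop = FALSE] +
        dxcol[ok2, 2L * c_in + seq_len(c_in), drop = FALSE]
      attr(dx, "n") <- cache$n; attr(dx, "len") <- cache$len
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = {
      list(dx = dout * cache$mask, grads = NULL)
    },
    maxpool = {
      n <- cache$n; len <- cache$len
      dx <- matrix(0, n * len, ncol(dout))
      dx[cache$odd, ] <- dout * cache$takes_odd
      dx[cache$odd + 1L, ] <- dout * (!cache$takes_odd)
      attr(dx, "n") <- n; attr(dx, "len") <- len
      list(dx = dx, grads = NULL)
    },
    bn = {
      xhat <- cache$xhat
      m <- nrow(dout)
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      if (cache$training) {
        scale <- layer$gamma * cache$inv_sd
        dx <- sweep(dout, 2, colMeans(dout)) -
          sweep(xhat, 2, colSums(dout * xhat) / m, "*")
        dx <- sweep(dx, 2, scale, "*")
      } else {
        dx <- sweep(dout, 2, layer$gamma * cache$inv_sd, "*")
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    flatten = {
      darr <- array(dout, c(cache$n, cache$len, cache$ch))
      dx <- matrix(aperm(darr, c(2, 1, 3)), cache$n * cache$len, cache$ch)
      attr(dx, "n") <- cache$n; attr(dx, "len") <- cache$len
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = tcrossprod(dout, layer$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    stop("unknown layer type ", layer$type)
  )
}

layer_update <- function(layer, grads, lr) {
  if (is.null(grads)) return(layer)
  for (nm in names(grads)) {
    layer[[nm]] <- layer[[nm]] - lr * grads[[nm]]
  }
  layer
}

## ---- whole-net passes ---------------------------------------------------

net_forward <- function(layers, x, training = FALSE, upto = length(layers)) {
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    st <- layer_forward(layers[[i]], x, training)
    x <- st$out
    caches[[i]] <- st$cache
    layers[[i]] <- st$layer
  }
  list(out = x, caches = caches, layers = layers)
}

# backpropagate from layer `from` down to 1; returns updated layers and dx
net_backward_update <- function(layers, caches, dout, lr,
                                from = length(layers)) {
  for (i in seq(from, 1L)) {
    bk <- layer_backward(layers[[i]], caches[[i]], dout)
    layers[[i]] <- layer_update(layers[[i]], bk$grads, lr)
    dout <- bk$dx
  }
  list(layers = layers, dx = dout)
}

## ---- softmax / cross-entropy --------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy of probability rows against integer labels in 0..K-1,
# with an epsilon floor guarding log(0)
cross_entropy <- function(prob, y, eps = 1e-12) {
  p <- prob[cbind(seq_len(nrow(prob)), y + 1L)]
  -mean(log(pmax(p, eps)))
}

onehot <- function(y, k = 5L) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}
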