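## Minimal convolutional-network engine used by the pose regressor.
##
## Layers operate on batches stored as (H, W, C, N) arrays. Convolutions
## (zero padding, arbitrary stride) are computed as im2col (C++) followed by
## a BLAS matrix multiply; the backward pass is the exact adjoint (col2im
## scatter-add). Batch normalization uses minibatch statistics while
## training and exponentially averaged running statistics at inference, so
## prediction is deterministic and batch-independent.
## This is deliberately small: conv / batchnorm / relu / flatten / linear /
## residual blocks and an Adam optimizer are all the pose head needs.

nn_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = 0L) {
  list(type = "conv", c_in = c_in, c_out = c_out, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}
nn_bnorm <- function(c) list(type = "bnorm", c = as.integer(c))
nn_relu <- function() list(type = "relu")
nn_flatten <- function() list(type = "flatten")
nn_linear <- function(d_in, d_out) list(type = "linear", d_in = d_in, d_out = d_out)
# residual block: main = conv3x3(pad 1)-bn-relu-conv3x3(pad 1)-bn over
# `stride`; shortcut = identity, or 1x1 projection conv + bn when the shape
# changes; relu after the add
nn_resblock <- function(c_in, c_out, stride = 1L) {
  list(type = "resblock", c_in = c_in, c_out = c_out, stride = as.integer(stride))
}

conv_out_px <- function(px, k, stride, pad = 0L) (px + 2L * pad - k) %/% stride + 1L

# He-scaled Gaussian initialization; uses the current RNG stream
nn_init_params <- function(layers) {
  conv_par <- function(c_in, c_out, k) {
    fan_in <- c_in * k^2
    matrix(rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)), c_out, fan_in)
  }
  lapply(layers, function(l) {
    switch(l$type,
      conv = list(W = conv_par(l$c_in, l$c_out, l$k), b = numeric(l$c_out)),
      bnorm = list(gamma = rep(1, l$c), beta = numeric(l$c)),
      linear = list(W = matrix(rnorm(l$d_out * l$d_in, sd = sqrt(2 / l$d_in)),
                               l$d_out, l$d_in),
                    b = numeric(l$d_out)),
      resblock = {
        p <- list(W1 = conv_par(l$c_in, l$c_out, 3L), b1 = numeric(l$c_out),
                  g1 = rep(1, l$c_out), be1 = numeric(l$c_out),
                  W2 = conv_par(l$c_out, l$c_out, 3L), b2 = numeric(l$c_out),
                  g2 = rep(1, l$c_out), be2 = numeric(l$c_out))
        if (l$stride != 1L || l$c_in != l$c_out) {
          p$Wp <- conv_par(l$c_in, l$c_out, 1L)
          p$bp <- numeric(l$c_out)
          p$gp <- rep(1, l$c_out)
          p$bep <- numeric(l$c_out)
        }
        p
      },
      list())
  })
}

# fresh running-statistics store matching the layer list
nn_init_stats <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "bnorm") {
      list(mean = numeric(l$c), var = rep(1, l$c), n = 0L)
    } else if (l$type == "resblock") {
      s <- list(bn1 = list(mean = numeric(l$c_out), var = rep(1, l$c_out), n = 0L),
                bn2 = list(mean = numeric(l$c_out), var = rep(1, l$c_out), n = 0L))
      if (l$stride != 1L || l$c_in != l$c_out) {
        s$bnp <- list(mean = numeric(l$c_out), var = rep(1, l$c_out), n = 0L)
      }
      s
    } else NULL
  })
}

conv_fwd <- function(x, dims, W, b, k, stride, pad = 0L) {
  H <- dims[1]; W_ <- dims[2]; C <- dims[3]; N <- dims[4]
  Ho <- conv_out_px(H, k, stride, pad); Wo <- conv_out_px(W_, k, stride, pad)
  cols <- im2col_cpp(x, dims, k, stride, pad)
  y <- W %*% cols + b
  out <- aperm(array(y, c(nrow(W), Ho, Wo, N)), c(2, 3, 1, 4))
  list(out = as.numeric(out), dims = c(Ho, Wo, nrow(W), N), cols = cols)
}

conv_bwd <- function(dout, out_dims, cache_cols, in_dims, W, k, stride, pad = 0L) {
  Ho <- out_dims[1]; Wo <- out_dims[2]; Cout <- out_dims[3]; N <- out_dims[4]
  dy <- aperm(array(dout, out_dims), c(3, 1, 2, 4))
  dim(dy) <- c(Cout, Ho * Wo * N)
  dW <- tcrossprod(dy, cache_cols) # dy %*% t(cols)
  db <- rowSums(dy)
  dcols <- crossprod(W, dy)
  dx <- col2im_cpp(dcols, in_dims, k, stride, pad)
  list(dx = dx, dW = dW, db = db)
}

# channel-wise batch normalization over (H, W, C, N); x is the flat array
bn_fwd <- function(x, dims, gamma, beta, stats, training, momentum = 0.9,
                   eps = 1e-5) {
  C <- dims[3]
  xm <- aperm(array(x, dims), c(1, 2, 4, 3))
  dim(xm) <- c(prod(dims) / C, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    if (stats$n == 0L) {
      stats$mean <- mu; stats$var <- v
    } else {
      stats$mean <- momentum * stats$mean + (1 - momentum) * mu
      stats$var <- momentum * stats$var + (1 - momentum) * v
    }
    stats$n <- stats$n + 1L
  } else {
    mu <- stats$mean; v <- stats$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- c(dims[1], dims[2], dims[4], dims[3])
  list(out = as.numeric(aperm(y, c(1, 2, 4, 3))), stats = stats,
       cache = list(xhat = xhat, invstd = invstd, dims = dims,
                    training = training))
}

bn_bwd <- function(dout, cache, gamma) {
  dims <- cache$dims; C <- dims[3]
  dy <- aperm(array(dout, dims), c(1, 2, 4, 3))
  dim(dy) <- c(prod(dims) / C, C)
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    t1 <- sweep(dy, 2, dbeta / m)
    t2 <- sweep(cache$xhat, 2, dgamma / m, `*`)
    dx <- sweep(t1 - t2, 2, gamma * cache$invstd, `*`)
  } else {
    dx <- sweep(dy, 2, gamma * cache$invstd, `*`)
  }
  dim(dx) <- c(dims[1], dims[2], dims[4], dims[3])
  list(dx = as.numeric(aperm(dx, c(1, 2, 4, 3))), dgamma = dgamma,
       dbeta = dbeta)
}

nn_forward <- function(layers, params, x, dims, stats = NULL,
                       training = FALSE) {
  if (is.null(stats)) stats <- nn_init_stats(layers)
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- params[[i]]
    if (l$type == "conv") {
      f <- conv_fwd(x, dims, p$W, p$b, l$k, l$stride, l$pad)
      caches[[i]] <- list(in_dims = dims, cols = f$cols, out_dims = f$dims)
      x <- f$out; dims <- f$dims
    } else if (l$type == "bnorm") {
      f <- bn_fwd(x, dims, p$gamma, p$beta, stats[[i]], training)
      stats[[i]] <- f$stats
      caches[[i]] <- f$cache
      x <- f$out
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (l$type == "flatten") {
      caches[[i]] <- list(in_dims = dims)
      dim(x) <- NULL
      x <- matrix(x, prod(dims[1:3]), dims[4])
      dims <- dim(x)
    } else if (l$type == "linear") {
      caches[[i]] <- list(x_in = x)
      x <- p$W %*% x + p$b
      dims <- dim(x)
    } else if (l$type == "resblock") {
      f1 <- conv_fwd(x, dims, p$W1, p$b1, 3L, l$stride, 1L)
      n1 <- bn_fwd(f1$out, f1$dims, p$g1, p$be1, stats[[i]]$bn1, training)
      stats[[i]]$bn1 <- n1$stats
      m1 <- n1$out > 0
      a1 <- n1$out * m1
      f2 <- conv_fwd(a1, f1$dims, p$W2, p$b2, 3L, 1L, 1L)
      n2 <- bn_fwd(f2$out, f2$dims, p$g2, p$be2, stats[[i]]$bn2, training)
      stats[[i]]$bn2 <- n2$stats
      if (!is.null(p$Wp)) {
        sc <- conv_fwd(x, dims, p$Wp, p$bp, 1L, l$stride, 0L)
        np <- bn_fwd(sc$out, sc$dims, p$gp, p$bep, stats[[i]]$bnp, training)
        stats[[i]]$bnp <- np$stats
        short <- np$out
        sc_cache <- list(cols = sc$cols, dims = sc$dims, bn = np$cache)
      } else {
        short <- x
        sc_cache <- list(dims = dims)
      }
      pre <- n2$out + short
      m2 <- pre > 0
      caches[[i]] <- list(in_dims = dims, cols1 = f1$cols, dims1 = f1$dims,
                          bn1 = n1$cache, mask1 = m1, cols2 = f2$cols,
                          dims2 = f2$dims, bn2 = n2$cache, mask2 = m2,
                          sc = sc_cache)
      x <- pre * m2
      dims <- f2$dims
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, dims = dims, caches = caches, stats = stats)
}

nn_backward <- function(layers, params, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; p <- params[[i]]; ch <- caches[[i]]
    if (l$type == "conv") {
      g <- conv_bwd(dout, ch$out_dims, ch$cols, ch$in_dims, p$W, l$k,
                    l$stride, l$pad)
      grads[[i]] <- list(W = g$dW, b = g$db)
      dout <- g$dx
    } else if (l$type == "bnorm") {
      g <- bn_bwd(dout, ch, p$gamma)
      grads[[i]] <- list(gamma = g$dgamma, beta = g$dbeta)
      dout <- g$dx
    } else if (l$type == "relu") {
      dout <- dout * ch$mask
    } else if (l$type == "flatten") {
      dout <- as.numeric(dout)
    } else if (l$type == "linear") {
      grads[[i]] <- list(W = tcrossprod(dout, ch$x_in), b = rowSums(dout))
      dout <- crossprod(p$W, dout)
    } else if (l$type == "resblock") {
      d_pre <- as.numeric(dout) * ch$mask2
      if (!is.null(p$Wp)) {
        gp <- bn_bwd(d_pre, ch$sc$bn, p$gp)
        g_sc <- conv_bwd(gp$dx, ch$sc$dims, ch$sc$cols, ch$in_dims, p$Wp, 1L,
                         l$stride, 0L)
        dx_short <- g_sc$dx
      } else {
        dx_short <- d_pre
      }
      g_n2 <- bn_bwd(d_pre, ch$bn2, p$g2)
      g2 <- conv_bwd(g_n2$dx, ch$dims2, ch$cols2, ch$dims1, p$W2, 3L, 1L, 1L)
      d_a1 <- g2$dx * ch$mask1
      g_n1 <- bn_bwd(d_a1, ch$bn1, p$g1)
      g1 <- conv_bwd(g_n1$dx, ch$dims1, ch$cols1, ch$in_dims, p$W1, 3L,
                     l$stride, 1L)
      gr <- list(W1 = g1$dW, b1 = g1$db, g1 = g_n1$dgamma, be1 = g_n1$dbeta,
                 W2 = g2$dW, b2 = g2$db, g2 = g_n2$dgamma, be2 = g_n2$dbeta)
      if (!is.null(p$Wp)) {
        gr$Wp <- g_sc$dW; gr$bp <- g_sc$db
        gr$gp <- gp$dgamma; gr$bep <- gp$dbeta
      }
      grads[[i]] <- gr
      dout <- g1$dx + dx_short
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      state$m[[i]][[nm]] <- b1 * state$m[[i]][[nm]] + (1 - b1) * g
      state$v[[i]][[nm]] <- b2 * state$v[[i]][[nm]] + (1 - b2) * g^2
      mh <- state$m[[i]][[nm]] / corr1
      vh <- state$v[[i]][[nm]] / corr2
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}
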