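## Minimal CPU neural-network engine ------------------------------------------
##
## Activations are 4-D arrays [H, W, C, N] (column-major) for convolutional
## stages and matrices [features, N] after flattening. Convolutions run through
## im2col + GEMM so the heavy arithmetic is BLAS; the backward pass is plain
## reverse-mode differentiation with col2im scatter-adds. Training uses Adam.
## The engine is sized for the compact networks in this package (tens of layers,
## <= a few tens of millions of parameters) and is deliberately framework-free:
## layers are plain lists, a model is a list of layers, and every stochastic
## step draws from R's RNG so runs are reproducible under set.seed().
##
## Leaf layer types: conv, bn, dense, relu, maxpool, gap, flatten, dropout.
## Composite type: resblock (main path + optional convolutional shortcut,
## post-add ReLU), used by both the basic (2-conv) and bottleneck blocks.

nn_init_weights <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / max(1, fan_in)))
}

layer_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = TRUE, name = "conv") {
  k <- as.integer(k)
  W <- matrix(nn_init_weights(c_out * k * k * c_in, k * k * c_in), nrow = c_out)
  structure(list(type = "conv", name = name, k = k, stride = as.integer(stride),
                 pad = as.integer(pad), c_in = as.integer(c_in),
                 c_out = as.integer(c_out), W = W,
                 b = if (bias) numeric(c_out) else NULL, trainable = TRUE),
            class = "hm_layer")
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5, name = "bn") {
  structure(list(type = "bn", name = name, c = as.integer(c),
                 gamma = rep(1, c), beta = numeric(c),
                 run_mean = numeric(c), run_var = rep(1, c),
                 momentum = momentum, eps = eps, trainable = TRUE),
            class = "hm_layer")
}

layer_dense <- function(d_in, d_out, bias = TRUE, name = "dense") {
  structure(list(type = "dense", name = name, d_in = as.integer(d_in),
                 d_out = as.integer(d_out),
                 W = matrix(nn_init_weights(d_out * d_in, d_in), nrow = d_out),
                 b = if (bias) numeric(d_out) else NULL, trainable = TRUE),
            class = "hm_layer")
}

layer_relu <- function(name = "relu") {
  structure(list(type = "relu", name = name), class = "hm_layer")
}

layer_maxpool <- function(k = 2L, stride = k, pad = 0L, name = "maxpool") {
  structure(list(type = "maxpool", name = name, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "hm_layer")
}

layer_gap <- function(name = "gap") {
  structure(list(type = "gap", name = name), class = "hm_layer")
}

layer_flatten <- function(name = "flatten") {
  structure(list(type = "flatten", name = name), class = "hm_layer")
}

layer_dropout <- function(rate = 0.25, name = "dropout") {
  structure(list(type = "dropout", name = name, rate = rate), class = "hm_layer")
}

## A residual block: `main` is a list of leaf layers (convs/bns/relus), the
## optional `shortcut` is a conv+bn pair for dimension-changing blocks; the
## block output is relu(main(x) + shortcut(x)).
layer_resblock <- function(main, shortcut = NULL, name = "resblock") {
  structure(list(type = "resblock", name = name, main = main,
                 shortcut = shortcut), class = "hm_layer")
}

## ---- geometry / im2col ------------------------------------------------------

conv_geometry <- function(k, stride, pad, c_in, H, W) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  off <- as.vector(outer(0:(k - 1L), Hp * (0:(k - 1L)), `+`))
  offc <- rep(off, c_in) + rep(Hp * Wp * (0:(c_in - 1L)), each = k * k)
  base <- as.vector(outer(1L + stride * (0:(Ho - 1L)),
                          Hp * stride * (0:(Wo - 1L)), `+`))
  idx <- outer(offc, base, `+`)
  list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = idx)
}

nn_pad <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(xp, idx, N, npix) {
  L <- ncol(idx)
  cols <- matrix(0, nrow(idx), L * N)
  xpv <- as.vector(xp)
  for (n in seq_len(N)) {
    cols[, ((n - 1L) * L + 1L):(n * L)] <- xpv[(n - 1L) * npix + idx]
  }
  cols
}


## Strided col2im: scatter-add of the k^2 kernel offsets back onto the
## padded input gradient.
col2im_strided <- function(dcols, k, stride, C, Hp, Wp, Ho, Wo, N) {
  dim(dcols) <- c(k, k, C, Ho, Wo, N)
  dxp <- array(0, c(Hp, Wp, C, N))
  for (dw in seq_len(k)) {
    wsel <- seq.int(dw, by = stride, length.out = Wo)
    for (dh in seq_len(k)) {
      hsel <- seq.int(dh, by = stride, length.out = Ho)
      sl <- dcols[dh, dw, , , , , drop = FALSE]
      dim(sl) <- c(C, Ho, Wo, N)
      acc <- dxp[hsel, wsel, , , drop = FALSE] + aperm(sl, c(2, 3, 1, 4))
      dxp[hsel, wsel, , ] <- acc
    }
  }
  dxp
}

## ---- leaf forward/backward --------------------------------------------------

conv_forward <- function(lay, x, train) {
  d <- dim(x); N <- d[4]
  g <- conv_geometry(lay$k, lay$stride, lay$pad, lay$c_in, d[1], d[2])
  xp <- nn_pad(x, lay$pad)
  cols <- im2col(xp, g$idx, N, g$Hp * g$Wp * d[3])
  out <- lay$W %*% cols
  if (!is.null(lay$b)) out <- out + lay$b
  y <- aperm(array(out, c(lay$c_out, g$Ho, g$Wo, N)), c(2, 3, 1, 4))
  list(y = y, cache = if (train) list(cols = cols, g = g, dims = d) else NULL,
       lay = lay)
}

conv_backward <- function(lay, cache, dy) {
  g <- cache$g; d <- cache$dims; N <- d[4]
  L <- g$Ho * g$Wo
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = lay$c_out)
  grads <- list(W = tcrossprod(dym, cache$cols))
  if (!is.null(lay$b)) grads$b <- rowSums(dym)
  dcols <- crossprod(lay$W, dym)
  dxp <- col2im_strided(dcols, lay$k, lay$stride, d[3], g$Hp, g$Wp,
                        g$Ho, g$Wo, N)
  p <- lay$pad
  dx <- if (p > 0L) {
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, grads = grads)
}

bn_forward <- function(lay, x, train) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  ## frozen batchnorm always runs in inference mode (running statistics and
  ## no buffer updates), so a frozen prefix computes fixed features
  batch_mode <- train && isTRUE(lay$trainable)
  if (batch_mode) {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm * xm) - mu^2, 0)
    lay$run_mean <- (1 - lay$momentum) * lay$run_mean + lay$momentum * mu
    lay$run_var <- (1 - lay$momentum) * lay$run_var + lay$momentum * v
  } else {
    mu <- lay$run_mean; v <- lay$run_var
  }
  inv <- 1 / sqrt(v + lay$eps)
  xh <- sweep(sweep(xm, 2L, mu), 2L, inv, `*`)
  ym <- sweep(sweep(xh, 2L, lay$gamma, `*`), 2L, lay$beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y,
       cache = if (train) list(xh = xh, inv = inv, dims = d,
                               batch_mode = batch_mode) else NULL,
       lay = lay)
}

bn_backward <- function(lay, cache, dy) {
  d <- cache$dims; C <- d[3]; m <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  dxh <- sweep(dym, 2L, lay$gamma, `*`)
  if (isTRUE(cache$batch_mode)) {
    t1 <- sweep(dxh, 2L, colSums(dxh) / m)
    t2 <- sweep(cache$xh, 2L, colSums(dxh * cache$xh) / m, `*`)
    dxm <- sweep(t1 - t2, 2L, cache$inv, `*`)
  } else {
    ## inference-mode statistics are constants w.r.t. the input
    dxm <- sweep(dxh, 2L, cache$inv, `*`)
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

dense_forward <- function(lay, x, train) {
  y <- lay$W %*% x
  if (!is.null(lay$b)) y <- y + lay$b
  list(y = y, cache = if (train) list(x = x) else NULL, lay = lay)
}

dense_backward <- function(lay, cache, dy) {
  grads <- list(W = dy %*% t(cache$x))
  if (!is.null(lay$b)) grads$b <- rowSums(dy)
  list(dx = crossprod(lay$W, dy), grads = grads)
}

relu_forward <- function(lay, x, train) {
  y <- pmax(x, 0)
  list(y = y, cache = if (train) list(mask = x > 0) else NULL, lay = lay)
}

relu_backward <- function(lay, cache, dy) {
  list(dx = dy * cache$mask, grads = NULL)
}

maxpool_forward <- function(lay, x, train) {
  d <- dim(x)
  M <- d[3] * d[4]
  x2 <- array(x, c(d[1], d[2], 1L, M))
  g <- conv_geometry(lay$k, lay$stride, lay$pad, 1L, d[1], d[2])
  xp <- nn_pad(x2, lay$pad, fill = -Inf)
  npix <- g$Hp * g$Wp
  cols <- im2col(xp, g$idx, M, npix)
  k2 <- nrow(cols)
  mx <- cols[1L, ]
  am <- rep(1L, length(mx))
  if (k2 > 1L) {
    for (r in 2L:k2) {
      sel <- cols[r, ] > mx
      mx[sel] <- cols[r, sel]
      am[sel] <- r
    }
  }
  y <- array(mx, c(g$Ho, g$Wo, d[3], d[4]))
  list(y = y, cache = if (train) list(g = g, am = am, dims = d) else NULL,
       lay = lay)
}

maxpool_backward <- function(lay, cache, dy) {
  g <- cache$g; d <- cache$dims
  M <- d[3] * d[4]; L <- g$Ho * g$Wo; npix <- g$Hp * g$Wp
  lpos <- rep.int(seq_len(L), M)
  mpos <- rep(seq_len(M), each = L)
  tgt <- g$idx[cbind(cache$am, lpos)] + (mpos - 1L) * npix
  dxp <- numeric(npix * M)
  acc <- rowsum(as.vector(dy), tgt)
  dxp[as.numeric(rownames(acc))] <- acc[, 1L]
  dxp <- array(dxp, c(g$Hp, g$Wp, d[3], d[4]))
  p <- lay$pad
  if (p > 0L) {
    dxp <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  }
  list(dx = dxp, grads = NULL)
}

gap_forward <- function(lay, x, train) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(y = y, cache = if (train) list(dims = d) else NULL, lay = lay)
}

gap_backward <- function(lay, cache, dy) {
  d <- cache$dims
  dx <- array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
  list(dx = dx, grads = NULL)
}

flatten_forward <- function(lay, x, train) {
  d <- dim(x)
  list(y = matrix(x, prod(d[1:3]), d[4]),
       cache = if (train) list(dims = d) else NULL, lay = lay)
}

flatten_backward <- function(lay, cache, dy) {
  list(dx = array(dy, cache$dims), grads = NULL)
}

dropout_forward <- function(lay, x, train) {
  if (!train || lay$rate <= 0) {
    return(list(y = x, cache = NULL, lay = lay))
  }
  keep <- 1 - lay$rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(y = x * mask, cache = list(mask = mask), lay = lay)
}

dropout_backward <- function(lay, cache, dy) {
  list(dx = dy * cache$mask, grads = NULL)
}

nn_leaf_forward <- function(lay, x, train) {
  switch(lay$type,
    conv = conv_forward(lay, x, train),
    bn = bn_forward(lay, x, train),
    dense = dense_forward(lay, x, train),
    relu = relu_forward(lay, x, train),
    maxpool = maxpool_forward(lay, x, train),
    gap = gap_forward(lay, x, train),
    flatten = flatten_forward(lay, x, train),
    dropout = dropout_forward(lay, x, train),
    stop("unknown layer type: ", lay$type))
}

nn_leaf_backward <- function(lay, cache, dy) {
  switch(lay$type,
    conv = conv_backward(lay, cache, dy),
    bn = bn_backward(lay, cache, dy),
    dense = dense_backward(lay, cache, dy),
    relu = relu_backward(lay, cache, dy),
    maxpool = maxpool_backward(lay, cache, dy),
    gap = gap_backward(lay, cache, dy),
    flatten = flatten_backward(lay, cache, dy),
    dropout = dropout_backward(lay, cache, dy),
    stop("unknown layer type: ", lay$type))
}

seq_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_leaf_forward(layers[[i]], x, train)
    x <- r$y
    caches[i] <- list(r$cache)
    layers[[i]] <- r$lay
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_leaf_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)
  }
  list(dx = dy, grads = grads)
}

## ---- model-level forward/backward ------------------------------------------

## Forward pass through a layer list. Returns the output, per-layer caches
## (train mode) and the possibly updated layers (batchnorm running stats).
nn_forward_layers <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    if (lay$type == "resblock") {
      rm_ <- seq_forward(lay$main, x, train)
      if (!is.null(lay$shortcut)) {
        rs <- seq_forward(lay$shortcut, x, train)
        s <- rs$y
        lay$shortcut <- rs$layers
      } else {
        rs <- NULL
        s <- x
      }
      pre <- rm_$y + s
      y <- pmax(pre, 0)
      caches[i] <- list(if (train) {
        list(main = rm_$caches, shortcut = rs$caches, mask = pre > 0)
      } else NULL)
      lay$main <- rm_$layers
      layers[[i]] <- lay
      x <- y
    } else {
      r <- nn_leaf_forward(lay, x, train)
      x <- r$y
      caches[i] <- list(r$cache)
      layers[[i]] <- r$lay
    }
  }
  list(y = x, caches = caches, layers = layers)
}

nn_backward_layers <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    lay <- layers[[i]]
    if (lay$type == "resblock") {
      dpre <- dy * caches[[i]]$mask
      rm_ <- seq_backward(lay$main, caches[[i]]$main, dpre)
      if (!is.null(lay$shortcut)) {
        rs <- seq_backward(lay$shortcut, caches[[i]]$shortcut, dpre)
        dx <- rm_$dx + rs$dx
        grads[[i]] <- list(main = rm_$grads, shortcut = rs$grads)
      } else {
        dx <- rm_$dx + dpre
        grads[[i]] <- list(main = rm_$grads, shortcut = NULL)
      }
      dy <- dx
    } else {
      r <- nn_leaf_backward(lay, caches[[i]], dy)
      dy <- r$dx
      grads[i] <- list(r$grads)
    }
  }
  list(dx = dy, grads = grads)
}

## ---- parameter walking ------------------------------------------------------

## Paths of parameter-bearing leaf layers in forward order. A path is a list
## usable with nn_get_layer / nn_set_layer; within a residual block the main
## path precedes the shortcut.
nn_param_paths <- function(layers) {
  paths <- list()
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    if (lay$type == "resblock") {
      for (j in seq_along(lay$main)) {
        if (!is.null(lay$main[[j]]$trainable)) {
          paths[[length(paths) + 1L]] <- list(i, "main", j)
        }
      }
      for (j in seq_along(lay$shortcut %||% list())) {
        if (!is.null(lay$shortcut[[j]]$trainable)) {
          paths[[length(paths) + 1L]] <- list(i, "shortcut", j)
        }
      }
    } else if (!is.null(lay$trainable)) {
      paths[[length(paths) + 1L]] <- list(i)
    }
  }
  paths
}

nn_get_layer <- function(layers, path) {
  if (length(path) == 1L) layers[[path[[1]]]] else
    layers[[path[[1]]]][[path[[2]]]][[path[[3]]]]
}

nn_set_layer <- function(layers, path, lay) {
  if (length(path) == 1L) {
    layers[[path[[1]]]] <- lay
  } else {
    layers[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- lay
  }
  layers
}

nn_get_grad <- function(grads, path) {
  if (length(path) == 1L) grads[[path[[1]]]] else
    grads[[path[[1]]]][[path[[2]]]][[path[[3]]]]
}

nn_param_names <- function(lay) {
  switch(lay$type,
    conv = if (is.null(lay$b)) "W" else c("W", "b"),
    dense = if (is.null(lay$b)) "W" else c("W", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

nn_layer_param_count <- function(lay) {
  sum(vapply(nn_param_names(lay), function(nm) length(lay[[nm]]), numeric(1)))
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function() {
  list(t = 0L, m = list(), v = list())
}

adam_step <- function(layers, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  paths <- nn_param_paths(layers)
  for (pi in seq_along(paths)) {
    path <- paths[[pi]]
    lay <- nn_get_layer(layers, path)
    if (!isTRUE(lay$trainable)) next
    g <- nn_get_grad(grads, path)
    if (is.null(g)) next
    for (nm in nn_param_names(lay)) {
      key <- paste(c(pi, nm), collapse = ".")
      gv <- g[[nm]]
      if (is.null(gv)) next
      m <- state$m[[key]] %||% (gv * 0)
      v <- state$v[[key]] %||% (gv * 0)
      m <- beta1 * m + (1 - beta1) * gv
      v <- beta2 * v + (1 - beta2) * gv * gv
      state$m[[key]] <- m
      state$v[[key]] <- v
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      lay[[nm]] <- lay[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    layers <- nn_set_layer(layers, path, lay)
  }
  list(layers = layers, state = state)
}

## Checksum over the parameters of selected layers (used to verify that frozen
## weights are bit-identical before and after training).
nn_param_checksum <- function(layers, trainable_only = FALSE,
                              frozen_only = FALSE) {
  paths <- nn_param_paths(layers)
  acc <- character(0)
  for (path in paths) {
    lay <- nn_get_layer(layers, path)
    if (trainable_only && !isTRUE(lay$trainable)) next
    if (frozen_only && isTRUE(lay$trainable)) next
    for (nm in nn_param_names(lay)) {
      acc <- c(acc, paste(format(sum(lay[[nm]]), digits = 17),
                          format(sum(lay[[nm]]^2), digits = 17)))
    }
  }
  paste(acc, collapse = "|")
}

## Length of the maximal leading run of top-level layers containing no
## trainable parameter leaf (the "frozen prefix"). Since frozen batchnorm
## runs in inference mode, this prefix is a fixed function whose outputs can
## be precomputed once per dataset.
nn_frozen_prefix <- function(layers) {
  has_trainable <- function(lay) {
    if (lay$type == "resblock") {
      any(vapply(c(lay$main, lay$shortcut %||% list()), has_trainable,
                 logical(1)))
    } else {
      !is.null(lay$trainable) && isTRUE(lay$trainable)
    }
  }
  n <- 0L
  for (lay in layers) {
    if (has_trainable(lay)) break
    n <- n + 1L
  }
  n
}

## Slice the sample dimension of an activation (matrix or 4-D array).
nn_slice_samples <- function(z, ii) {
  if (is.matrix(z)) z[, ii, drop = FALSE] else z[, , , ii, drop = FALSE]
}

nn_n_samples <- function(z) {
  if (is.matrix(z)) ncol(z) else dim(z)[4]
}
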