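# Minimal convolutional-network engine in base R: 4-D arrays (H, W, C, N),
# im2col convolutions backed by BLAS matrix products, explicit
# backpropagation, and a decoupled-weight-decay Adam optimizer. Scope is
# exactly what the temperature regressor needs: conv / batchnorm / relu /
# maxpool / global-average-pool / flatten / dense plus residual blocks.

nn_conv <- function(kh, kw, cin, cout, stride = c(1L, 1L), pad = c(1L, 1L),
                    bias = TRUE) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(stats::rnorm(cout * kh * kw * cin, 0, sd), cout),
       b = if (bias) numeric(cout) else NULL)
}

nn_dense <- function(din, dout) {
  list(type = "dense", din = din, dout = dout,
       W = matrix(stats::rnorm(dout * din, 0, sqrt(2 / din)), dout),
       b = numeric(dout))
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", ch = ch, eps = eps, momentum = momentum,
       gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch), initialized = FALSE)
}

nn_relu <- function() list(type = "relu")
nn_flatten <- function() list(type = "flatten")
nn_gap <- function() list(type = "gap")

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

nn_resblock <- function(cin, cout, stride = 1L) {
  down <- if (stride != 1L || cin != cout) {
    list(nn_conv(1L, 1L, cin, cout, stride = c(stride, stride),
                 pad = c(0L, 0L), bias = FALSE), nn_bn(cout))
  }
  list(type = "resblock",
       conv1 = nn_conv(3L, 3L, cin, cout, stride = c(stride, stride),
                       pad = c(1L, 1L), bias = FALSE),
       bn1 = nn_bn(cout),
       conv2 = nn_conv(3L, 3L, cout, cout, pad = c(1L, 1L), bias = FALSE),
       bn2 = nn_bn(cout),
       down = down)
}

pad_hw <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * ph, d[2] + 2L * pw, d[3], d[4]))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), , ] <- x
  xp
}

# Linear indices of all (kernel offset) x (output position) pairs inside the
# zero-padded array; rows are ordered (a, b, c) to match the weight layout,
# columns (i, j, n).
im2col_idx <- function(pdim, kh, kw, sh, sw, hout, wout) {
  Hp <- as.integer(pdim[1]); Wp <- as.integer(pdim[2])
  C <- as.integer(pdim[3]); N <- as.integer(pdim[4])
  off <- as.vector(outer(outer(0:(kh - 1L), Hp * (0:(kw - 1L)), "+"),
                         (Hp * Wp) * (0:(C - 1L)), "+"))
  base <- as.vector(outer(outer(sh * (0:(hout - 1L)),
                                (Hp * sw) * (0:(wout - 1L)), "+"),
                          (Hp * Wp * C) * (0:(N - 1L)), "+"))
  outer(as.integer(off), as.integer(base), "+") + 1L
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  sh <- layer$stride[1]; sw <- layer$stride[2]
  ph <- layer$pad[1]; pw <- layer$pad[2]
  xp <- pad_hw(x, ph, pw)
  pd <- dim(xp)
  hout <- (pd[1] - layer$kh) %/% sh + 1L
  wout <- (pd[2] - layer$kw) %/% sw + 1L
  idx <- im2col_idx(pd, layer$kh, layer$kw, sh, sw, hout, wout)
  col <- matrix(xp[idx], nrow(idx))
  y <- layer$W %*% col
  if (!is.null(layer$b)) y <- y + layer$b
  out <- aperm(array(t(y), c(hout, wout, d[4], layer$cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(col = col, idx = idx, pdim = pd, xdim = d,
                               hout = hout, wout = wout))
}

conv_backward <- function(layer, cache, dout) {
  dy <- aperm(dout, c(3, 1, 2, 4))
  dim(dy) <- c(layer$cout, ncol(cache$col))
  dW <- dy %*% t(cache$col)
  db <- if (!is.null(layer$b)) rowSums(dy) else NULL
  dcol <- crossprod(layer$W, dy)
  dxp <- numeric(prod(cache$pdim))
  idx <- cache$idx
  # rows sharing a spatial kernel offset (a, b) hit disjoint targets across
  # all input channels, so they can be scattered in one vectorized pass
  khw <- layer$kh * layer$kw
  for (r in seq_len(khw)) {
    sel <- seq.int(r, nrow(idx), by = khw)
    tg <- idx[sel, ]
    dxp[tg] <- dxp[tg] + dcol[sel, ]
  }
  dim(dxp) <- cache$pdim
  ph <- layer$pad[1]; pw <- layer$pad[2]
  d <- cache$xdim
  dx <- dxp[ph + seq_len(d[1]), pw + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1], d[2], 1L, d[3] * d[4])
  xp <- pad_hw(xr, layer$pad, layer$pad)
  pd <- dim(xp)
  hout <- (pd[1] - layer$k) %/% layer$stride + 1L
  wout <- (pd[2] - layer$k) %/% layer$stride + 1L
  idx <- im2col_idx(pd, layer$k, layer$k, layer$stride, layer$stride,
                    hout, wout)
  col <- matrix(xp[idx], nrow(idx))
  am <- max.col(t(col), ties.method = "first")
  sel <- cbind(am, seq_len(ncol(col)))
  out <- array(col[sel], c(hout, wout, d[3], d[4]))
  list(out = out,
       cache = list(flat = idx[sel], pdim = pd, xdim = d,
                    pad = layer$pad))
}

maxpool_backward <- function(layer, cache, dout) {
  dxp <- numeric(prod(cache$pdim))
  agg <- rowsum(as.vector(dout), cache$flat)
  dxp[as.numeric(rownames(agg))] <- agg
  dim(dxp) <- cache$pdim
  d <- cache$xdim
  p <- cache$pad
  dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), 1L, , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, grads = NULL)
}

# Batch norm on the (H*W) x (C*N) collapsed view: column j belongs to
# channel ((j-1) mod C) + 1, so per-channel statistics are row sums of a
# (C, N) reshape of the column sums -- no aperm of the 4-D array needed.
bn_forward <- function(layer, x, training) {
  d <- dim(x)
  C <- d[3]; N <- d[4]; hw <- d[1] * d[2]
  m <- hw * N
  xm <- x
  dim(xm) <- c(hw, C * N)
  if (training || !layer$initialized) {
    cs <- colSums(xm); dim(cs) <- c(C, N)
    cs2 <- colSums(xm^2); dim(cs2) <- c(C, N)
    mu <- rowSums(cs) / m
    v <- rowSums(cs2) / m - mu^2
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, rep(mu, N)), 2, rep(istd, N), "*")
  out <- sweep(sweep(xhat, 2, rep(layer$gamma, N), "*"), 2,
               rep(layer$beta, N), "+")
  dim(out) <- d
  upd <- NULL
  if (training) {
    mom <- layer$momentum
    upd <- list(run_mean = (1 - mom) * layer$run_mean + mom * mu,
                run_var = (1 - mom) * layer$run_var + mom * v,
                initialized = TRUE)
  }
  list(out = out,
       cache = list(xhat = xhat, istd = istd, xdim = d),
       update = upd)
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$xdim
  C <- d[3]; N <- d[4]; hw <- d[1] * d[2]
  m <- hw * N
  dy <- dout
  dim(dy) <- c(hw, C * N)
  s1 <- colSums(dy); dim(s1) <- c(C, N)
  s2 <- colSums(dy * cache$xhat); dim(s2) <- c(C, N)
  dbeta <- rowSums(s1)
  dgamma <- rowSums(s2)
  # means of dxhat and dxhat*xhat per channel follow from the same sums
  mdx <- layer$gamma * dbeta / m
  mdxx <- layer$gamma * dgamma / m
  dxhat <- sweep(dy, 2, rep(layer$gamma, N), "*")
  dxm <- sweep(dxhat, 2, rep(mdx, N)) -
    sweep(cache$xhat, 2, rep(mdxx, N), "*")
  dxm <- sweep(dxm, 2, rep(cache$istd, N), "*")
  dim(dxm) <- d
  list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = c(conv_forward(layer, x), list(layer = NULL)),
    dense = {
      y <- layer$W %*% x + layer$b
      list(out = y, cache = list(x = x))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[1:3]), d[4])
      list(out = y, cache = list(xdim = d))
    },
    gap = {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      list(out = matrix(colMeans(xm), d[3], d[4]), cache = list(xdim = d))
    },
    maxpool = maxpool_forward(layer, x),
    bn = bn_forward(layer, x, training),
    resblock = resblock_forward(layer, x, training),
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dout),
    dense = list(dx = crossprod(layer$W, dout),
                 grads = list(W = dout %*% t(cache$x), b = rowSums(dout))),
    relu = list(dx = dout * cache$mask, grads = NULL),
    flatten = {
      dx <- dout
      dim(dx) <- cache$xdim
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$xdim
      hw <- d[1] * d[2]
      dx <- array(rep(as.vector(dout) / hw, each = hw), d)
      list(dx = dx, grads = NULL)
    },
    maxpool = maxpool_backward(layer, cache, dout),
    bn = bn_backward(layer, cache, dout),
    resblock = resblock_backward(layer, cache, dout),
    stop("unknown layer type ", layer$type))
}

resblock_forward <- function(layer, x, training) {
  f1 <- conv_forward(layer$conv1, x)
  b1 <- bn_forward(layer$bn1, f1$out, training)
  r1 <- pmax(b1$out, 0)
  f2 <- conv_forward(layer$conv2, r1)
  b2 <- bn_forward(layer$bn2, f2$out, training)
  if (!is.null(layer$down)) {
    fd <- conv_forward(layer$down[[1]], x)
    bd <- bn_forward(layer$down[[2]], fd$out, training)
    short <- bd$out
    dcache <- list(conv = fd$cache, bn = bd$cache)
    dupd <- bd$update
  } else {
    short <- x
    dcache <- NULL
    dupd <- NULL
  }
  s <- b2$out + short
  out <- pmax(s, 0)
  upd <- list(bn1 = b1$update, bn2 = b2$update, down_bn = dupd)
  list(out = out,
       cache = list(c1 = f1$cache, b1 = b1$cache, m1 = b1$out > 0,
                    c2 = f2$cache, b2 = b2$cache, down = dcache,
                    mout = s > 0, has_down = !is.null(layer$down)),
       update = upd)
}

resblock_backward <- function(layer, cache, dout) {
  ds <- dout * cache$mout
  g2 <- bn_backward(layer$bn2, cache$b2, ds)
  k2 <- conv_backward(layer$conv2, cache$c2, g2$dx)
  dr1 <- k2$dx * cache$m1
  g1 <- bn_backward(layer$bn1, cache$b1, dr1)
  k1 <- conv_backward(layer$conv1, cache$c1, g1$dx)
  if (cache$has_down) {
    gd <- bn_backward(layer$down[[2]], cache$down$bn, ds)
    kd <- conv_backward(layer$down[[1]], cache$down$conv, gd$dx)
    dshort <- kd$dx
    down_grads <- list(conv = kd$grads, bn = gd$grads)
  } else {
    dshort <- ds
    down_grads <- NULL
  }
  list(dx = k1$dx + dshort,
       grads = list(conv1 = k1$grads, bn1 = g1$grads,
                    conv2 = k2$grads, bn2 = g2$grads, down = down_grads))
}

apply_bn_update <- function(layer, upd) {
  if (is.null(upd)) return(layer)
  layer$run_mean <- upd$run_mean
  layer$run_var <- upd$run_var
  layer$initialized <- upd$initialized
  layer
}

#' Forward pass through a network
#'
#' @param net A `vt_net` built by [build_model()].
#' @param x Input array `(H, W, C, N)`.
#' @param training Use batch statistics and record caches for
#'   backpropagation.
#' @return List with `out` (the head output, a `1 x N` matrix for the
#'   regression models), `caches`, and the (possibly updated) `net`.
#' @keywords internal
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[l]], x, training)
    x <- fw$out
    caches[[l]] <- fw$cache
    if (training && !is.null(fw$update)) {
      lay <- net$layers[[l]]
      if (lay$type == "bn") {
        net$layers[[l]] <- apply_bn_update(lay, fw$update)
      } else if (lay$type == "resblock") {
        lay$bn1 <- apply_bn_update(lay$bn1, fw$update$bn1)
        lay$bn2 <- apply_bn_update(lay$bn2, fw$update$bn2)
        if (!is.null(lay$down)) {
          lay$down[[2]] <- apply_bn_update(lay$down[[2]], fw$update$down_bn)
        }
        net$layers[[l]] <- lay
      }
    }
  }
  list(out = x, caches = caches, net = net)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    bk <- layer_backward(net$layers[[l]], caches[[l]], dout)
    dout <- bk$dx
    grads[l] <- list(bk$grads)
  }
  list(dx = dout, grads = grads)
}

# ---- AdamW -----------------------------------------------------------------

param_fields <- function(layer) {
  switch(layer$type,
    conv = if (is.null(layer$b)) "W" else c("W", "b"),
    dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

adamw_init_layer <- function(layer) {
  if (layer$type == "resblock") {
    st <- list(conv1 = adamw_init_layer(layer$conv1),
               bn1 = adamw_init_layer(layer$bn1),
               conv2 = adamw_init_layer(layer$conv2),
               bn2 = adamw_init_layer(layer$bn2))
    if (!is.null(layer$down)) {
      st$down <- list(conv = adamw_init_layer(layer$down[[1]]),
                      bn = adamw_init_layer(layer$down[[2]]))
    }
    return(st)
  }
  fs <- param_fields(layer)
  if (length(fs) == 0) return(NULL)
  stats::setNames(lapply(fs, function(f) {
    list(m = layer[[f]] * 0, v = layer[[f]] * 0)
  }), fs)
}

adamw_init <- function(net) {
  list(t = 0L, layers = lapply(net$layers, adamw_init_layer))
}

adamw_step_layer <- function(layer, grads, st, lr, beta1, beta2, eps, wd, t) {
  if (is.null(grads)) return(list(layer = layer, state = st))
  if (layer$type == "resblock") {
    parts <- c("conv1", "bn1", "conv2", "bn2")
    for (p in parts) {
      r <- adamw_step_layer(layer[[p]], grads[[p]], st[[p]],
                            lr, beta1, beta2, eps, wd, t)
      layer[[p]] <- r$layer
      st[[p]] <- r$state
    }
    if (!is.null(layer$down) && !is.null(grads$down)) {
      r1 <- adamw_step_layer(layer$down[[1]], grads$down$conv, st$down$conv,
                             lr, beta1, beta2, eps, wd, t)
      r2 <- adamw_step_layer(layer$down[[2]], grads$down$bn, st$down$bn,
                             lr, beta1, beta2, eps, wd, t)
      layer$down[[1]] <- r1$layer
      layer$down[[2]] <- r2$layer
      st$down <- list(conv = r1$state, bn = r2$state)
    }
    return(list(layer = layer, state = st))
  }
  for (f in param_fields(layer)) {
    g <- grads[[f]]
    if (is.null(g)) next
    s <- st[[f]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    # decoupled weight decay: applied to weights, not biases / bn params
    decay <- if (f == "W") wd else 0
    layer[[f]] <- layer[[f]] - lr * (mh / (sqrt(vh) + eps) + decay * layer[[f]])
    st[[f]] <- s
  }
  list(layer = layer, state = st)
}

adamw_update <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  for (l in seq_along(net$layers)) {
    r <- adamw_step_layer(net$layers[[l]], grads[[l]], state$layers[[l]],
                          lr, beta1, beta2, eps, weight_decay, state$t)
    net$layers[[l]] <- r$layer
    state$layers[l] <- list(r$state)
  }
  list(net = net, state = state)
}

count_layer_params <- function(layer) {
  if (is.null(layer)) return(0)
  if (layer$type == "resblock") {
    n <- count_layer_params(layer$conv1) + count_layer_params(layer$bn1) +
      count_layer_params(layer$conv2) + count_layer_params(layer$bn2)
    if (!is.null(layer$down)) {
      n <- n + count_layer_params(layer$down[[1]]) +
        count_layer_params(layer$down[[2]])
    }
    return(n)
  }
  sum(vapply(param_fields(layer), function(f) length(layer[[f]]), numeric(1)))
}

#' Number of trainable parameters in a model
#'
#' Counts convolution and dense weights/biases and batch-norm scale/shift
#' parameters (running statistics are buffers, not parameters).
#'
#' @param net A `vt_net`.
#' @return Integer-valued count.
#' @export
n_params <- function(net) {
  sum(vapply(net$layers, count_layer_params, numeric(1)))
}
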