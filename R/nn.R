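# Internal neural-network primitives.
#
# Convolutional feature maps use layout (H, W, N, C): with R's column-major
# storage, any contiguous reshape to a (H*W*N) x C matrix exposes channels
# as columns, so a 3x3 "same" convolution is nine shifted (H*W*N) x Cin by
# Cin x Cout BLAS matmuls. Vector features use (features x N) matrices.
# Every layer has an explicit hand-derived backward pass; correctness is
# pinned by finite-difference gradient tests.

conv_init <- function(k, cin, cout) {
  list(type = "conv",
       W = array(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

# Memoized im2col gather indices, keyed by the padded-array geometry.
.conv_idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, N, C) {
  key <- paste(H, W, N, C, sep = "x")
  idx <- .conv_idx_cache[[key]]
  if (is.null(idx)) {
    Hp <- H + 2L; Wp <- W + 2L
    base <- rep(seq_len(H), times = W * N) +
      Hp * rep(rep(seq_len(W) - 1L, each = H), times = N) +
      (Hp * Wp) * rep(seq_len(N) - 1L, each = H * W)
    off <- rep(0:2, times = 3L * C) + Hp * rep(rep(0:2, each = 3L), times = C) +
      (Hp * Wp * N) * rep(seq_len(C) - 1L, each = 9L)
    idx <- rep(base, times = length(off)) +
      rep(off, each = length(base))  # (m) x (9C) gather table, linear indices
    .conv_idx_cache[[key]] <- idx
  }
  idx
}

conv_forward <- function(layer, X) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(layer$W)[4]
  Xpad <- array(0, c(H + 2, W + 2, N, Cin))
  Xpad[2:(H + 1), 2:(W + 1), , ] <- X
  m <- H * W * N
  Xcol <- Xpad[im2col_idx(H, W, N, Cin)]
  dim(Xcol) <- c(m, 9L * Cin)
  Wm <- layer$W
  dim(Wm) <- c(9L * Cin, Cout)
  Y <- Xcol %*% Wm + rep(layer$b, each = m)
  dim(Y) <- c(H, W, N, Cout)
  list(out = Y, cache = list(Xcol = Xcol, dims = d))
}

conv_backward <- function(layer, cache, dY) {
  d <- cache$dims; H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(layer$W)[4]
  m <- H * W * N
  dYpad <- array(0, c(H + 2, W + 2, N, Cout))
  dYpad[2:(H + 1), 2:(W + 1), , ] <- dY
  dim(dY) <- c(m, Cout)
  dW <- crossprod(cache$Xcol, dY)       # (9*Cin) x Cout, (i,j,cin) row order
  dim(dW) <- c(3L, 3L, Cin, Cout)
  # input gradient: correlate dY with the 180-degree-rotated kernel, via the
  # same single-gather im2col on the padded upstream gradient
  dYcol <- dYpad[im2col_idx(H, W, N, Cout)]
  dim(dYcol) <- c(m, 9L * Cout)
  Wrot <- layer$W[3:1, 3:1, , , drop = FALSE]     # mirror both kernel axes
  Wrot <- aperm(Wrot, c(1, 2, 4, 3))              # rows (i,j,cout), cols cin
  dim(Wrot) <- c(9L * Cout, Cin)
  dX <- dYcol %*% Wrot
  dim(dX) <- c(H, W, N, Cin)
  list(dX = dX, grads = list(W = dW, b = colSums(dY)))
}

pool_forward <- function(layer, X) {
  d <- dim(X); r <- seq(1, d[1], 2); c <- seq(1, d[2], 2)
  out <- (X[r, c, , , drop = FALSE] + X[r + 1, c, , , drop = FALSE] +
          X[r, c + 1, , , drop = FALSE] + X[r + 1, c + 1, , , drop = FALSE]) / 4
  list(out = out, cache = list(dims = d))
}

pool_backward <- function(layer, cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  r <- seq(1, d[1], 2); c <- seq(1, d[2], 2)
  g <- dY / 4
  dX[r, c, , ] <- g; dX[r + 1, c, , ] <- g
  dX[r, c + 1, , ] <- g; dX[r + 1, c + 1, , ] <- g
  list(dX = dX, grads = NULL)
}

upsample_forward <- function(layer, X) {
  d <- dim(X)
  Y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  r <- seq(1, 2 * d[1], 2); c <- seq(1, 2 * d[2], 2)
  Y[r, c, , ] <- X; Y[r + 1, c, , ] <- X
  Y[r, c + 1, , ] <- X; Y[r + 1, c + 1, , ] <- X
  list(out = Y, cache = list(dims = d))
}

upsample_backward <- function(layer, cache, dY) {
  d <- cache$dims
  r <- seq(1, 2 * d[1], 2); c <- seq(1, 2 * d[2], 2)
  dX <- dY[r, c, , , drop = FALSE] + dY[r + 1, c, , , drop = FALSE] +
    dY[r, c + 1, , , drop = FALSE] + dY[r + 1, c + 1, , , drop = FALSE]
  list(dX = dX, grads = NULL)
}

bn_init <- function(cc) {
  list(type = "bn", gamma = rep(1, cc), beta = numeric(cc),
       run_mean = numeric(cc), run_var = rep(1, cc),
       momentum = 0.1, eps = 1e-5)
}

bn_forward <- function(layer, X, train) {
  d <- dim(X); cc <- d[4]; m <- prod(d[1:3])
  M <- matrix(X, m, cc)
  if (train) {
    mu <- colMeans(M)
    xc <- M - rep(mu, each = m)
    v <- colMeans(xc * xc)
    invsd <- 1 / sqrt(v + layer$eps)
    xhat <- xc * rep(invsd, each = m)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
    cache <- list(xc = xc, invsd = invsd, xhat = xhat, dims = d, m = m)
  } else {
    invsd <- 1 / sqrt(layer$run_var + layer$eps)
    xhat <- (M - rep(layer$run_mean, each = m)) * rep(invsd, each = m)
    cache <- NULL
  }
  Y <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
  list(out = array(Y, d), cache = cache, layer = layer)
}

bn_backward <- function(layer, cache, dY) {
  m <- cache$m; d <- cache$dims; cc <- d[4]
  dYm <- matrix(dY, m, cc)
  dxhat <- dYm * rep(layer$gamma, each = m)
  dvar <- colSums(dxhat * cache$xc) * (-0.5) * cache$invsd^3
  dmu <- -colSums(dxhat) * cache$invsd
  dX <- dxhat * rep(cache$invsd, each = m) +
    cache$xc * rep(2 * dvar / m, each = m) + rep(dmu / m, each = m)
  list(dX = array(dX, d),
       grads = list(gamma = colSums(dYm * cache$xhat), beta = colSums(dYm)))
}

relu_forward <- function(layer, X) {
  mask <- X > 0
  list(out = X * mask, cache = list(mask = mask))
}
relu_backward <- function(layer, cache, dY) list(dX = dY * cache$mask, grads = NULL)

sigmoid_forward <- function(layer, X) {
  Y <- 1 / (1 + exp(-X))
  list(out = Y, cache = list(Y = Y))
}
sigmoid_backward <- function(layer, cache, dY)
  list(dX = dY * cache$Y * (1 - cache$Y), grads = NULL)

linear_init <- function(nin, nout) {
  list(type = "linear",
       W = matrix(rnorm(nout * nin) * sqrt(2 / nin), nout, nin),
       b = numeric(nout))
}

linear_forward <- function(layer, X) {
  list(out = layer$W %*% X + layer$b, cache = list(X = X))
}

linear_backward <- function(layer, cache, dY) {
  list(dX = crossprod(layer$W, dY),
       grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
}

dropout_forward <- function(layer, X, train) {
  if (!train || layer$p == 0) return(list(out = X, cache = list(mask = NULL)))
  mask <- (matrix(runif(length(X)), nrow(X), ncol(X)) >= layer$p) / (1 - layer$p)
  list(out = X * mask, cache = list(mask = mask))
}
dropout_backward <- function(layer, cache, dY) {
  if (is.null(cache$mask)) return(list(dX = dY, grads = NULL))
  list(dX = dY * cache$mask, grads = NULL)
}

# flatten (H, W, N, C) -> (H*W*C) x N; cache records dims for the inverse.
flatten_forward <- function(layer, X) {
  d <- dim(X)
  Y <- matrix(aperm(X, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  list(out = Y, cache = list(dims = d))
}
flatten_backward <- function(layer, cache, dY) {
  d <- cache$dims
  list(dX = aperm(array(dY, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)),
       grads = NULL)
}

unflatten_forward <- function(layer, X) {
  d <- c(layer$h, layer$w, layer$c)
  N <- ncol(X)
  list(out = aperm(array(X, c(d[1], d[2], d[3], N)), c(1, 2, 4, 3)),
       cache = list(N = N))
}
unflatten_backward <- function(layer, cache, dY) {
  d <- dim(dY)
  list(dX = matrix(aperm(dY, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]),
       grads = NULL)
}

# Forward through a layer list. Returns output, per-layer caches, and the
# (possibly updated, for BN running stats) layer list.
net_forward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, X), pool = pool_forward(l, X),
      upsample = upsample_forward(l, X), bn = bn_forward(l, X, train),
      relu = relu_forward(l, X), sigmoid = sigmoid_forward(l, X),
      linear = linear_forward(l, X), dropout = dropout_forward(l, X, train),
      flatten = flatten_forward(l, X), unflatten = unflatten_forward(l, X),
      stopf("unknown layer type '%s'", l$type))
    X <- r$out
    caches[i] <- list(r$cache)  # not [[<-: a NULL cache must keep its slot
    if (!is.null(r$layer)) layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

# Backward through a layer list; returns input gradient and per-layer grads.
net_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_backward(l, caches[[i]], dY),
      pool = pool_backward(l, caches[[i]], dY),
      upsample = upsample_backward(l, caches[[i]], dY),
      bn = bn_backward(l, caches[[i]], dY),
      relu = relu_backward(l, caches[[i]], dY),
      sigmoid = sigmoid_backward(l, caches[[i]], dY),
      linear = linear_backward(l, caches[[i]], dY),
      dropout = dropout_backward(l, caches[[i]], dY),
      flatten = flatten_backward(l, caches[[i]], dY),
      unflatten = unflatten_backward(l, caches[[i]], dY))
    dY <- r$dX
    grads[i] <- list(r$grads)
  }
  list(dX = dY, grads = grads)
}

take_samples <- function(X, idx) {
  if (is.matrix(X)) X[, idx, drop = FALSE] else X[, , idx, , drop = FALSE]
}

n_samples <- function(X) if (is.matrix(X)) ncol(X) else dim(X)[3]

# Recalibrate batch-normalization running statistics with a dedicated pass:
# chunk t contributes its batch statistics with weight 1/t, so the running
# values end as the average over chunks of the training data. No parameter
# updates occur.
calibrate_bn <- function(layers, X, chunk = 200) {
  n <- n_samples(X)
  starts <- seq(1, n, by = chunk)
  for (t in seq_along(starts)) {
    idx <- starts[t]:min(starts[t] + chunk - 1, n)
    for (i in seq_along(layers))
      if (layers[[i]]$type == "bn") layers[[i]]$momentum <- 1 / t
    layers <- net_forward(layers, take_samples(X, idx), train = TRUE)$layers
  }
  for (i in seq_along(layers))
    if (layers[[i]]$type == "bn") layers[[i]]$momentum <- 0.1
  layers
}

# Evaluation-mode forward in memory-bounded chunks; binds matrix outputs by
# column (latent vectors) and 4-D outputs along the sample dimension.
forward_chunked <- function(layers, X, chunk = 200) {
  n <- n_samples(X)
  starts <- seq(1, n, by = chunk)
  outs <- lapply(seq_along(starts), function(t) {
    idx <- starts[t]:min(starts[t] + chunk - 1, n)
    net_forward(layers, take_samples(X, idx), train = FALSE)$out
  })
  if (is.matrix(outs[[1]])) return(do.call(cbind, outs))
  od <- dim(outs[[1]])
  out <- array(0, c(od[1], od[2], n, od[4]))
  at <- 0L
  for (t in seq_along(outs)) {
    nt <- dim(outs[[t]])[3]
    out[, , at + seq_len(nt), ] <- outs[[t]]
    at <- at + nt
  }
  out
}

# ---- Adam optimizer over a set of layer lists -------------------------------

adam_init <- function(nets) {
  st <- list(t = 0L, m = list(), v = list())
  for (nn in names(nets)) for (i in seq_along(nets[[nn]])) {
    for (p in intersect(c("W", "b", "gamma", "beta"), names(nets[[nn]][[i]]))) {
      key <- paste(nn, i, p, sep = ".")
      st$m[[key]] <- nets[[nn]][[i]][[p]] * 0
      st$v[[key]] <- nets[[nn]][[i]][[p]] * 0
    }
  }
  st
}

adam_step <- function(nets, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nn in names(grads)) for (i in seq_along(grads[[nn]])) {
    g <- grads[[nn]][[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      key <- paste(nn, i, p, sep = ".")
      st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * g[[p]]
      st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * g[[p]]^2
      nets[[nn]][[i]][[p]] <- nets[[nn]][[i]][[p]] -
        lr * (st$m[[key]] / bc1) / (sqrt(st$v[[key]] / bc2) + eps)
    }
  }
  list(nets = nets, state = st)
}
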