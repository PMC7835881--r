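# Differentiable building blocks for the Siamese network. Each *_fwd
# returns list(out, cache); each *_bwd takes the cache and the upstream
# gradient and returns the input gradient plus any parameter gradients.
# Feature maps are (H, W, D, C) arrays; convolution weights are stored as
# Cout x (Cin*27) matrices matching the im2col row order of the C++ kernel.

conv_fwd <- function(x, W, b) {
  d <- dim(x)
  y <- conv3d_fwd_cpp(x, d, W, b)
  list(out = y, cache = list(x = x, dims = d, W = W))
}

conv_bwd <- function(cache, dy) {
  g <- conv3d_bwd_cpp(cache$x, cache$dims, dy, cache$W)
  list(dx = g$dx, dW = g$dW, db = as.numeric(g$db))
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_bwd <- function(cache, dy) {
  dy[!cache] <- 0
  dy
}

# leaky rectifier for the convolution stacks: at widths of a few channels
# a permanently dead channel wipes out a whole encoder level, so the
# negative side keeps a small slope
leaky_alpha <- 0.05

lrelu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- leaky_alpha * x[!mask]
  list(out = x, cache = mask)
}

lrelu_bwd <- function(cache, dy) {
  dy[!cache] <- leaky_alpha * dy[!cache]
  dy
}

# 2x2x2 max pooling, stride 2. The input is reshaped to
# (2, H/2, 2, W/2, 2, D/2, C); the winner among the 8 within-cell slices
# is tracked for the backward scatter (ties: lowest slice index).
maxpool_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[1] / 2; w2 <- d[2] / 2; d2 <- d[3] / 2; C <- d[4]
  dim(x) <- c(2, h2, 2, w2, 2, d2, C)
  y <- NULL; arg <- NULL
  n <- 0L
  for (ck in 1:2) for (cj in 1:2) for (ci in 1:2) {
    n <- n + 1L
    s <- x[ci, , cj, , ck, , , drop = FALSE]
    dim(s) <- c(h2, w2, d2, C)
    if (is.null(y)) {
      y <- s
      arg <- array(1L, dim(s))
    } else {
      m <- s > y
      y[m] <- s[m]
      arg[m] <- n
    }
  }
  list(out = y, cache = list(arg = arg, dims = d))
}

maxpool_bwd <- function(cache, dy) {
  d <- cache$dims
  h2 <- d[1] / 2; w2 <- d[2] / 2; d2 <- d[3] / 2; C <- d[4]
  dx <- array(0, c(2, h2, 2, w2, 2, d2, C))
  n <- 0L
  for (ck in 1:2) for (cj in 1:2) for (ci in 1:2) {
    n <- n + 1L
    g <- dy
    g[cache$arg != n] <- 0
    dx[ci, , cj, , ck, , ] <- g
  }
  dim(dx) <- d
  dx
}

# 1D trilinear 2x upsampling operator (half-pixel-centre convention) as a
# dense 2n x n matrix; applied separably along each spatial axis.
upsample_matrix <- function(n) {
  U <- matrix(0, 2 * n, n)
  for (o in 0:(2 * n - 1)) {
    src <- o / 2 - 0.25
    lo <- floor(src)
    fr <- src - lo
    lo <- min(max(lo, 0), n - 1)
    hi <- min(lo + 1, n - 1)
    if (src < 0) { lo <- hi <- 0; fr <- 0 }
    if (src > n - 1) { lo <- hi <- n - 1; fr <- 0 }
    U[o + 1, lo + 1] <- U[o + 1, lo + 1] + (1 - fr)
    U[o + 1, hi + 1] <- U[o + 1, hi + 1] + fr
  }
  U
}

apply_axis <- function(x, M, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dim(xp) <- c(d[axis], prod(d[-axis]))
  y <- M %*% xp
  dy <- d
  dy[axis] <- nrow(M)
  dim(y) <- dy[perm]
  aperm(y, order(perm))
}

upsample_fwd <- function(x) {
  d <- dim(x)
  U1 <- upsample_matrix(d[1]); U2 <- upsample_matrix(d[2])
  U3 <- upsample_matrix(d[3])
  y <- apply_axis(apply_axis(apply_axis(x, U1, 1), U2, 2), U3, 3)
  list(out = y, cache = list(U1 = U1, U2 = U2, U3 = U3))
}

upsample_bwd <- function(cache, dy) {
  apply_axis(apply_axis(apply_axis(dy, t(cache$U1), 1), t(cache$U2), 2),
             t(cache$U3), 3)
}

# Dual squeeze-and-excitation. Channel branch: global-average-pool each
# channel to v, recalibrate with sigmoid(w2 relu(w1 v)) and scale channels.
# Spatial branch: 1x1x1 convolution w3 across channels, sigmoid, scale
# voxels. The two branches are fused by elementwise addition.
duse_fwd <- function(x, w1, w2, w3) {
  d <- dim(x)
  N <- prod(d[1:3]); C <- d[4]
  xm <- x
  dim(xm) <- c(N, C)
  v <- colMeans(xm)
  z1 <- as.numeric(w1 %*% v)
  h <- pmax(z1, 0)
  vhat <- sigmoid(as.numeric(w2 %*% h))
  Fsc <- sweep(xm, 2, vhat, "*")
  m <- as.numeric(xm %*% w3)
  mhat <- sigmoid(m)
  Fcs <- xm * mhat
  out <- Fsc + Fcs
  dim(out) <- d
  list(out = out,
       cache = list(xm = xm, v = v, z1 = z1, h = h, vhat = vhat,
                    mhat = mhat, w1 = w1, w2 = w2, w3 = w3, dims = d))
}

duse_bwd <- function(cache, dy) {
  d <- cache$dims
  N <- prod(d[1:3]); C <- d[4]
  dim(dy) <- c(N, C)
  xm <- cache$xm
  # channel branch
  dxm <- sweep(dy, 2, cache$vhat, "*")
  dvhat <- colSums(dy * xm)
  dz2 <- dvhat * cache$vhat * (1 - cache$vhat)
  dw2 <- outer(dz2, cache$h)
  dh <- as.numeric(t(cache$w2) %*% dz2)
  dz1 <- ifelse(cache$z1 > 0, dh, 0)
  dw1 <- outer(dz1, cache$v)
  dv <- as.numeric(t(cache$w1) %*% dz1)
  dxm <- dxm + matrix(dv / N, nrow = N, ncol = C, byrow = TRUE)
  # spatial branch
  dxm <- dxm + dy * cache$mhat
  dmhat <- rowSums(dy * xm)
  dm <- dmhat * cache$mhat * (1 - cache$mhat)
  dw3 <- as.numeric(t(xm) %*% dm)
  dxm <- dxm + outer(dm, cache$w3)
  dim(dxm) <- d
  list(dx = dxm, dw1 = dw1, dw2 = dw2, dw3 = dw3)
}

linear_fwd <- function(x, W, b) {
  list(out = as.numeric(W %*% x + b), cache = list(x = x, W = W))
}

linear_bwd <- function(cache, dy) {
  list(dx = as.numeric(t(cache$W) %*% dy),
       dW = outer(dy, cache$x), db = dy)
}
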