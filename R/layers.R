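# Minimal CPU neural-network primitives on (H, W, C, N) arrays with
# hand-written backward passes. Convolutions run as im2col (compiled, see
# src/conv_ops.cpp) + one BLAS gemm in each direction; everything is double
# precision and deterministic.

# --- 3x3 "same" convolution ------------------------------------------------

# weight layout: W is (Cout x 9*Cin); column (o-1)*Cin + cin corresponds to
# kernel offset o in 1..9 (dh = (o-1) %% 3 + 1, dw = (o-1) %/% 3 + 1, i.e.
# the tap at input position (h + dh - 2, w + dw - 2)) and input channel cin.

conv3_forward <- function(X, Wm, b) {
  d <- dim(X)
  out <- cs_conv3_fwd(X, Wm, b, d[1L], d[2L], d[3L], d[4L])
  list(out = out, X = X, dims = d)   # im2col is rebuilt per image in backward
}

conv3_backward <- function(dY, cache, Wm) {
  d <- cache$dims
  cs_conv3_bwd(cache$X, dY, Wm, d[1L], d[2L], d[3L], d[4L])
}

# --- 1x1 convolution (channel mixing) --------------------------------------

conv1_forward <- function(X, Wm, b) {
  d <- dim(X)
  Xm <- cs_hwcn_to_pixfirst(X, d[1L], d[2L], d[3L], d[4L])
  Y <- tcrossprod(Xm, Wm)
  out <- cs_pixfirst_to_hwcn(Y, d[1L], d[2L], d[4L], b)
  list(out = out, Xm = Xm, dims = d)
}

conv1_backward <- function(dY, cache, Wm) {
  d <- cache$dims
  dYm <- cs_hwcn_to_pixfirst(dY, d[1L], d[2L], nrow(Wm), d[4L])
  dW <- crossprod(dYm, cache$Xm)
  db <- colSums(dYm)
  dXm <- dYm %*% Wm
  dX <- cs_pixfirst_to_hwcn(dXm, d[1L], d[2L], d[4L])
  list(dX = dX, dW = dW, db = db)
}

# --- channelwise affine (trainable scale and shift) ------------------------

affine_forward <- function(X, gamma, beta) {
  d <- dim(X)
  hw <- d[1L] * d[2L]
  X * rep(gamma, each = hw) + rep(beta, each = hw)
}

affine_backward <- function(dY, X, gamma) {
  d <- dim(X)
  hw <- d[1L] * d[2L]
  per_cn <- matrix(dY * X, hw, d[3L] * d[4L])
  dgamma <- rowSums(matrix(.colSums(per_cn, hw, d[3L] * d[4L]), d[3L], d[4L]))
  per_cn2 <- matrix(dY, hw, d[3L] * d[4L])
  dbeta <- rowSums(matrix(.colSums(per_cn2, hw, d[3L] * d[4L]), d[3L], d[4L]))
  list(dX = dY * rep(gamma, each = hw), dgamma = dgamma, dbeta = dbeta)
}

# --- batch normalization ----------------------------------------------------

# per-channel statistics over (H, W, N); eps guards constant channels.
# training mode returns caches and updated running moments; eval mode uses
# the running moments (no batch coupling at inference).
bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(X)
  hw <- d[1L] * d[2L]
  if (training) {
    per_cn <- matrix(.colSums(matrix(X, hw, d[3L] * d[4L]), hw, d[3L] * d[4L]),
                     d[3L], d[4L])
    mu <- rowSums(per_cn) / (hw * d[4L])
    Xc <- X - rep(mu, each = hw)
    per_cn2 <- matrix(.colSums(matrix(Xc^2, hw, d[3L] * d[4L]), hw, d[3L] * d[4L]),
                      d[3L], d[4L])
    v <- rowSums(per_cn2) / (hw * d[4L])
    inv <- 1 / sqrt(v + eps)
    Xhat <- Xc * rep(inv, each = hw)
    out <- Xhat * rep(gamma, each = hw) + rep(beta, each = hw)
    list(out = out, Xhat = Xhat, inv = inv,
         run_mean = momentum * run_mean + (1 - momentum) * mu,
         run_var = momentum * run_var + (1 - momentum) * v)
  } else {
    inv <- 1 / sqrt(run_var + eps)
    scale <- gamma * inv
    shift <- beta - run_mean * scale
    list(out = X * rep(scale, each = hw) + rep(shift, each = hw))
  }
}

bn_backward <- function(dY, cache, gamma) {
  d <- dim(dY)
  hw <- d[1L] * d[2L]
  m <- hw * d[4L]
  sum_c <- function(A) rowSums(matrix(
    .colSums(matrix(A, hw, d[3L] * d[4L]), hw, d[3L] * d[4L]), d[3L], d[4L]))
  dbeta <- sum_c(dY)
  dgamma <- sum_c(dY * cache$Xhat)
  g <- dY * rep(gamma, each = hw)
  dX <- rep(cache$inv / m, each = hw) *
    (m * g - rep(sum_c(g), each = hw) -
       cache$Xhat * rep(sum_c(g * cache$Xhat), each = hw))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- nonlinearities ---------------------------------------------------------

relu_forward <- function(X, slope = 0) {
  if (slope == 0) pmax(X, 0) else ifelse(X > 0, X, slope * X)
}

relu_backward <- function(dY, X, slope = 0) {
  if (slope == 0) dY * (X > 0) else dY * ifelse(X > 0, 1, slope)
}

# --- 2x2 stride-2 pooling and nearest upsampling ---------------------------

idx_odd <- function(n) seq.int(1L, n, 2L)

avgpool_forward <- function(X) {
  d <- dim(X)
  io <- idx_odd(d[1L]); jo <- idx_odd(d[2L])
  (X[io, jo, , , drop = FALSE] + X[io + 1L, jo, , , drop = FALSE] +
     X[io, jo + 1L, , , drop = FALSE] + X[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

avgpool_backward <- function(dY) {
  upsample_nearest(dY) / 4
}

maxpool_forward <- function(X) {
  d <- dim(X)
  io <- idx_odd(d[1L]); jo <- idx_odd(d[2L])
  q <- list(X[io, jo, , , drop = FALSE], X[io + 1L, jo, , , drop = FALSE],
            X[io, jo + 1L, , , drop = FALSE], X[io + 1L, jo + 1L, , , drop = FALSE])
  out <- pmax(q[[1L]], q[[2L]], q[[3L]], q[[4L]])
  # first-match tie-break over the four quadrant positions
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4L)
  for (i in 1:4) {
    m <- (q[[i]] == out) & !taken
    taken <- taken | m
    masks[[i]] <- m
  }
  list(out = out, masks = masks)
}

maxpool_backward <- function(dY, cache) {
  d <- dim(dY)
  dX <- array(0, c(2L * d[1L], 2L * d[2L], d[3L], d[4L]))
  io <- idx_odd(2L * d[1L]); jo <- idx_odd(2L * d[2L])
  dX[io, jo, , ] <- dY * cache$masks[[1L]]
  dX[io + 1L, jo, , ] <- dY * cache$masks[[2L]]
  dX[io, jo + 1L, , ] <- dY * cache$masks[[3L]]
  dX[io + 1L, jo + 1L, , ] <- dY * cache$masks[[4L]]
  dX
}

upsample_nearest <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

downsample_sum <- function(dY) {
  d <- dim(dY)
  io <- idx_odd(d[1L]); jo <- idx_odd(d[2L])
  dY[io, jo, , , drop = FALSE] + dY[io + 1L, jo, , , drop = FALSE] +
    dY[io, jo + 1L, , , drop = FALSE] + dY[io + 1L, jo + 1L, , , drop = FALSE]
}

concat_channels <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- A
  out[, , da[3L] + seq_len(db[3L]), ] <- B
  out
}
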