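# Analytic (sub)gradient of the separation loss with respect to S, used by
# the trainer. Conventions at non-smooth points: sign(0) = 0 for the l1/TV
# terms, zero gradient for zero per-pixel channel vectors in the l2,1 term,
# and U V' from the thin SVD for the nuclear norm (the standard subgradient
# choice; repeated singular values follow svd()'s basis). These are the same
# conventions the numeric value of the loss is paired with throughout
# training.

# returns list(value = loss, grad = dLoss/dS), both for the full batch
separation_loss_value_grad <- function(D, S, config) {
  d <- batch_dims(D)
  L <- D - S

  L1 <- unfold_background(L)
  sv <- svd(L1)
  nuc <- sum(sv$d)
  g_nuc <- -fold_background(sv$u %*% t(sv$v), d$H, d$W, d$c)

  lam <- config$lambda_sparse
  if (d$c == 1L) {
    l21 <- sum(abs(S))
    g_sp <- lam * sign(S)
  } else {
    nrm2 <- S[, , 1L, , drop = FALSE]^2
    for (k in 2:d$c) nrm2 <- nrm2 + S[, , k, , drop = FALSE]^2
    nrm <- sqrt(nrm2)
    l21 <- sum(nrm)
    scale <- array(0, dim(nrm))
    nz <- nrm > 0
    scale[nz] <- 1 / nrm[nz]
    g_sp <- array(0, dim(S))
    for (k in seq_len(d$c)) g_sp[, , k, ] <- lam * S[, , k, , drop = FALSE] * scale
  }

  tv_total <- 0
  g_tv <- NULL
  if (config$lambda_tv > 0) {
    g_tv <- array(0, dim(S))
    full <- config$tv_full_boundary
    H <- d$H; W <- d$W
    rh <- seq_len(H - 1L); cw <- seq_len(W - 1L)
    for (j in seq_len(d$n)) for (k in seq_len(d$c)) {
      img <- S[, , k, j]
      g <- matrix(0, H, W)
      if (full) {
        dv <- img[-1L, , drop = FALSE] - img[-H, , drop = FALSE]
        dh <- img[, -1L, drop = FALSE] - img[, -W, drop = FALSE]
        tv_total <- tv_total + sum(abs(dv)) + sum(abs(dh))
        sv_ <- sign(dv); sh_ <- sign(dh)
        g[-1L, ] <- g[-1L, ] + sv_;  g[-H, ] <- g[-H, ] - sv_
        g[, -1L] <- g[, -1L] + sh_;  g[, -W] <- g[, -W] - sh_
      } else {
        dv <- img[-1L, cw, drop = FALSE] - img[rh, cw, drop = FALSE]
        dh <- img[rh, -1L, drop = FALSE] - img[rh, cw, drop = FALSE]
        tv_total <- tv_total + sum(abs(dv)) + sum(abs(dh))
        sv_ <- sign(dv); sh_ <- sign(dh)
        g[-1L, cw] <- g[-1L, cw] + sv_;  g[rh, cw] <- g[rh, cw] - sv_
        g[rh, -1L] <- g[rh, -1L] + sh_;  g[rh, cw] <- g[rh, cw] - sh_
      }
      g_tv[, , k, j] <- g
    }
  }

  value <- nuc + lam * l21 + config$lambda_tv * tv_total
  grad <- g_nuc + g_sp
  if (!is.null(g_tv)) grad <- grad + config$lambda_tv * g_tv
  list(value = value, grad = grad,
       terms = c(nuclear = nuc, l21 = lam * l21, tv = config$lambda_tv * tv_total))
}
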