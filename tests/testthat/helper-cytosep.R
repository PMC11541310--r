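# Shared fixtures. Everything is generated in code; seeds are fixed so the
# suite is deterministic.

rand_batch <- function(H = 5, W = 4, C = 1, N = 3, seed = 1, signed = FALSE) {
  withr::with_seed(seed, {
    v <- if (signed) rnorm(H * W * C * N, 0, 0.3) else runif(H * W * C * N)
    array(v, c(H, W, C, N))
  })
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# independent brute-force oracles -------------------------------------------

oracle_tv <- function(img, full_boundary = FALSE) {
  H <- nrow(img); W <- ncol(img)
  total <- 0
  if (full_boundary) {
    for (h in 1:(H - 1)) for (w in 1:W)
      total <- total + abs(img[h + 1, w] - img[h, w])
    for (h in 1:H) for (w in 1:(W - 1))
      total <- total + abs(img[h, w + 1] - img[h, w])
  } else {
    for (h in 1:(H - 1)) for (w in 1:(W - 1))
      total <- total + abs(img[h + 1, w] - img[h, w]) +
        abs(img[h, w + 1] - img[h, w])
  }
  total
}

oracle_nuclear <- function(M) {
  # via eigenvalues of the Gram matrix, independent of svd()
  ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
  sum(sqrt(pmax(ev, 0)))
}

oracle_l21 <- function(M) {
  total <- 0
  for (j in seq_len(ncol(M))) total <- total + sqrt(sum(M[, j]^2))
  total
}

# vectorization index oracles: value of image j, channel k, pixel (h, w)
# must appear at the documented flat positions
oracle_unfold_background <- function(x) {
  d <- dim(x)
  M <- matrix(0, d[3] * d[1] * d[2], d[4])
  for (j in seq_len(d[4])) for (k in seq_len(d[3]))
    for (h in seq_len(d[1])) for (w in seq_len(d[2]))
      M[(k - 1) * d[1] * d[2] + (h - 1) * d[2] + w, j] <- x[h, w, k, j]
  M
}

oracle_unfold_foreground <- function(x) {
  d <- dim(x)
  M <- matrix(0, d[3], d[1] * d[2] * d[4])
  for (j in seq_len(d[4])) for (h in seq_len(d[1])) for (w in seq_len(d[2]))
    for (k in seq_len(d[3]))
      M[k, (j - 1) * d[1] * d[2] + (h - 1) * d[2] + w] <- x[h, w, k, j]
  M
}

# independent component-count oracle: iterative minimum-label propagation
# over the 8-neighborhood until fixpoint (a different algorithm from the
# package's flood fill)
oracle_count_components <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (h in seq_len(H)) for (w in seq_len(W)) {
      if (!mask[h, w]) next
      nb <- lab[max(1, h - 1):min(H, h + 1), max(1, w - 1):min(W, w + 1)]
      nb <- nb[nb > 0L]
      new[h, w] <- min(nb)
    }
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[lab > 0L]))
}

# a small, quick-to-train study setup used by trainer tests
tiny_study <- function() {
  batch <- generate_batch(synthetic_config(
    n_images = 14L, height = 16L, width = 16L, background_rank = 1L,
    cell_count_range = c(1L, 2L), cell_radius_range = c(2.5, 4),
    debris_pixel_rate = 0, noise_sd = 0.005, seed = 7L))
  list(train = batch$D[, , , 1:10, drop = FALSE],
       val = batch$D[, , , 11:14, drop = FALSE],
       val_masks = batch$masks[, , 11:14],
       net = network_config(depth = 2L, base_channels = 4L, in_channels = 1L),
       cfg = train_config(batch_size = 5L, learning_rate = 2e-2, epochs = 4L,
                          lambda_tv = 0.01, seed = 3L))
}

# the end-to-end synthetic study used by the acceptance experiments:
# 48 training + 16 held-out grayscale 64x64 images, rank-2 backgrounds,
# 1-4 cells, debris rate 0.001. Trained once per TV setting and memoized
# so the separation and ablation checks share the fits.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  batch <- generate_batch(synthetic_config(n_images = 64L, height = 64L,
                                           width = 64L, background_rank = 2L,
                                           cell_count_range = c(1L, 4L),
                                           debris_pixel_rate = 0.001,
                                           noise_sd = 0.01, seed = 12L))
  .study_cache$study <- list(
    train = batch$D[, , , 1:48, drop = FALSE],
    test = batch$D[, , , 49:64, drop = FALSE],
    masks = batch$masks[, , 49:64])
  .study_cache$study
}

acceptance_run <- function(lambda_tv) {
  key <- paste0("fit_", lambda_tv)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  st <- acceptance_study()
  fit <- train(st$train, st$test,
               network_config(depth = 3L, base_channels = 16L,
                              in_channels = 1L, nonlinearity = "leaky_relu"),
               train_config(batch_size = 4L, learning_rate = 1e-2,
                            lr_decay = 0.95, selection_every = 2L,
                            epochs = 30L, lambda_tv = lambda_tv, seed = 4L),
               val_masks = st$masks)
  S <- predict(fit, st$test)$S
  sel <- select_threshold(S, st$masks)
  .study_cache[[key]] <- list(fit = fit, S = S, tau = sel$tau, dice = sel$dice)
  .study_cache[[key]]
}
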