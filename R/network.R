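#' Encoder-decoder network configuration
#'
#' A U-Net-style fully convolutional encoder-decoder that maps an input
#' image to its signed foreground `S`; the background is `L = D - S`. The
#' default skip wiring is the dual-frame variant: at each decoder level the
#' upsampled decoder feature map is subtracted from the matching encoder
#' feature map, and the difference is merged (concatenated) with the
#' decoder path — balancing coarse reconstruction against fine detail.
#' Plain encoder-feature concatenation is available as a fallback. The
#' final layer is a linear 1x1 convolution so predicted cells can take
#' negative values (cells are darker than the background).
#'
#' @param depth number of resolution levels (>= 1); images must have
#'   height and width divisible by `2^(depth - 1)`.
#' @param base_channels feature maps at the first level; doubled at each
#'   deeper level.
#' @param in_channels input channel count c (1 or 3).
#' @param skip_mode `"dual_frame_subtraction"` (default) or
#'   `"concatenation"`.
#' @param normalization `"batch"` (batch normalization with trainable
#'   per-channel scale and shift, default; inference uses running
#'   moments, so prediction stays per-image), `"affine"` (scale and
#'   shift only) or `"none"`.
#' @param nonlinearity `"relu"` (default) or `"leaky_relu"` (slope 0.01).
#' @param downsample `"average_pool"` (default) or `"max_pool"`.
#' @param upsample `"nearest"` (nearest-neighbor interpolation; the only
#'   choice, kept as an enum for forward compatibility).
#' @param final_init `"zero"` (default: the network starts at S = 0,
#'   L = D) or `"random"`.
#' @return A list of class `"network_config"`.
#' @export
network_config <- function(depth = 4L, base_channels = 64L, in_channels = 1L,
                           skip_mode = c("dual_frame_subtraction", "concatenation"),
                           normalization = c("batch", "affine", "none"),
                           nonlinearity = c("relu", "leaky_relu"),
                           downsample = c("average_pool", "max_pool"),
                           upsample = "nearest",
                           final_init = c("zero", "random")) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  in_channels <- as.integer(in_channels)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (!in_channels %in% c(1L, 3L)) stop("in_channels must be 1 or 3")
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = in_channels,
                 skip_mode = match.arg(skip_mode),
                 normalization = match.arg(normalization),
                 nonlinearity = match.arg(nonlinearity),
                 downsample = match.arg(downsample),
                 upsample = match.arg(upsample),
                 final_init = match.arg(final_init)),
            class = "network_config")
}

level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

relu_slope <- function(cfg) if (cfg$nonlinearity == "leaky_relu") 0.01 else 0

# He-normal conv parameters; affine layers start at identity
init_conv <- function(cout, cin, k) {
  list(W = matrix(rnorm(cout * k * cin, 0, sqrt(2 / (k * cin))), cout, k * cin),
       b = numeric(cout))
}

block_names <- function(cfg) {
  nm <- character(0)
  for (l in seq_len(cfg$depth)) nm <- c(nm, paste0("enc", l, "_c1"), paste0("enc", l, "_c2"))
  for (l in rev(seq_len(cfg$depth - 1L))) nm <- c(nm, paste0("up", l),
                                                  paste0("dec", l, "_c1"),
                                                  paste0("dec", l, "_c2"))
  nm
}

block_channels <- function(cfg, name) {
  # returns c(cin, cout) for each named 3x3 conv block
  if (grepl("^enc", name)) {
    l <- as.integer(sub("^enc(\\d+)_c\\d$", "\\1", name))
    cout <- level_channels(cfg, l)
    cin <- if (grepl("_c2$", name)) cout
           else if (l == 1L) cfg$in_channels else level_channels(cfg, l - 1L)
    c(cin, cout)
  } else if (grepl("^up", name)) {
    l <- as.integer(sub("^up(\\d+)$", "\\1", name))
    c(level_channels(cfg, l + 1L), level_channels(cfg, l))
  } else {
    l <- as.integer(sub("^dec(\\d+)_c\\d$", "\\1", name))
    cout <- level_channels(cfg, l)
    cin <- if (grepl("_c1$", name)) 2L * cout else cout
    c(cin, cout)
  }
}

#' Build a separation network with deterministic initialization
#'
#' Convolution kernels are He-normal initialized from the seed; affine
#' normalization layers start at identity. With the default
#' `final_init = "zero"` the final 1x1 convolution starts at zero, so the
#' untrained network outputs `S = 0` and `L = D`.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed; the same config and seed give bit-identical
#'   parameters.
#' @return An object of class `"separation_model"`: list with `config` and
#'   `params` (named list of arrays).
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  with_private_seed(seed, {
    params <- list()
    bn <- list()
    for (nm in block_names(cfg)) {
      ch <- block_channels(cfg, nm)
      cv <- init_conv(ch[2L], ch[1L], 9L)
      params[[paste0(nm, "_W")]] <- cv$W
      params[[paste0(nm, "_b")]] <- cv$b
      if (cfg$normalization %in% c("affine", "batch")) {
        params[[paste0(nm, "_g")]] <- rep(1, ch[2L])
        params[[paste0(nm, "_s")]] <- rep(0, ch[2L])
      }
      if (cfg$normalization == "batch") {
        bn[[paste0(nm, "_mean")]] <- rep(0, ch[2L])
        bn[[paste0(nm, "_var")]] <- rep(1, ch[2L])
      }
    }
    c1 <- level_channels(cfg, 1L)
    if (cfg$final_init == "zero") {
      params$final_W <- matrix(0, cfg$in_channels, c1)
    } else {
      params$final_W <- matrix(rnorm(cfg$in_channels * c1, 0, sqrt(1 / c1)),
                               cfg$in_channels, c1)
    }
    params$final_b <- numeric(cfg$in_channels)
    structure(list(config = cfg, params = params, bn = bn),
              class = "separation_model")
  })
}

#' @export
print.separation_model <- function(x, ...) {
  cat(sprintf(
    "separation_model: depth %d, base %d channels, c=%d, skip=%s (%d parameters)\n",
    x$config$depth, x$config$base_channels, x$config$in_channels,
    x$config$skip_mode, n_parameters(x)))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a `separation_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

check_divisible <- function(model, D) {
  d <- batch_dims(D)
  div <- 2L^(model$config$depth - 1L)
  if (d$H %% div != 0L || d$W %% div != 0L)
    stop(sprintf(
      "image size %d x %d not divisible by %d (required by depth %d)",
      d$H, d$W, div, model$config$depth))
  if (d$c != model$config$in_channels)
    stop(sprintf("model expects %d channels, got %d",
                 model$config$in_channels, d$c))
  invisible(d)
}

# one conv3 -> normalization -> relu block; returns output, cache and
# (in batch-norm training mode) updated running moments
block_forward <- function(X, params, nm, cfg, bn = NULL, training = FALSE) {
  cv <- conv3_forward(X, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]])
  pre <- cv$out
  aff_in <- NULL
  bn_cache <- NULL
  bn_update <- NULL
  if (cfg$normalization == "affine") {
    aff_in <- pre
    pre <- affine_forward(pre, params[[paste0(nm, "_g")]], params[[paste0(nm, "_s")]])
  } else if (cfg$normalization == "batch") {
    r <- bn_forward(pre, params[[paste0(nm, "_g")]], params[[paste0(nm, "_s")]],
                    bn[[paste0(nm, "_mean")]], bn[[paste0(nm, "_var")]],
                    training = training)
    if (training) {
      bn_cache <- list(Xhat = r$Xhat, inv = r$inv)
      bn_update <- list(mean = r$run_mean, var = r$run_var)
    }
    pre <- r$out
  }
  out <- relu_forward(pre, relu_slope(cfg))
  list(out = out, conv = cv, aff_in = aff_in, pre = pre,
       bn_cache = bn_cache, bn_update = bn_update)
}

block_backward <- function(dY, cache, params, nm, cfg, grads) {
  dpre <- relu_backward(dY, cache$pre, relu_slope(cfg))
  if (cfg$normalization == "affine") {
    ab <- affine_backward(dpre, cache$aff_in, params[[paste0(nm, "_g")]])
    grads[[paste0(nm, "_g")]] <- grads[[paste0(nm, "_g")]] %+g% ab$dgamma
    grads[[paste0(nm, "_s")]] <- grads[[paste0(nm, "_s")]] %+g% ab$dbeta
    dpre <- ab$dX
  } else if (cfg$normalization == "batch") {
    if (is.null(cache$bn_cache))
      stop("backward requires a training-mode forward pass")
    bb <- bn_backward(dpre, cache$bn_cache, params[[paste0(nm, "_g")]])
    grads[[paste0(nm, "_g")]] <- grads[[paste0(nm, "_g")]] %+g% bb$dgamma
    grads[[paste0(nm, "_s")]] <- grads[[paste0(nm, "_s")]] %+g% bb$dbeta
    dpre <- bb$dX
  }
  cb <- conv3_backward(dpre, cache$conv, params[[paste0(nm, "_W")]])
  grads[[paste0(nm, "_W")]] <- grads[[paste0(nm, "_W")]] %+g% cb$dW
  grads[[paste0(nm, "_b")]] <- grads[[paste0(nm, "_b")]] %+g% cb$db
  list(dX = cb$dX, grads = grads)
}

`%+g%` <- function(a, b) if (is.null(a)) b else a + b

# full forward pass; keep_cache = TRUE retains every intermediate needed by
# network_backward; training = TRUE uses batch statistics in the
# normalization layers and returns their updated running moments
network_forward <- function(model, D, keep_cache = FALSE, training = FALSE) {
  cfg <- model$config
  params <- model$params
  bn <- model$bn
  caches <- if (keep_cache) list() else NULL
  track_bn <- training && cfg$normalization == "batch"
  run_block <- function(x, nm) {
    bf <- block_forward(x, params, nm, cfg, bn = bn, training = training)
    if (keep_cache) caches[[nm]] <<- bf
    if (track_bn) {
      bn[[paste0(nm, "_mean")]] <<- bf$bn_update$mean
      bn[[paste0(nm, "_var")]] <<- bf$bn_update$var
    }
    bf$out
  }
  E <- vector("list", cfg$depth)
  x <- D
  pool <- cfg$downsample
  for (l in seq_len(cfg$depth)) {
    if (l > 1L) {
      if (pool == "average_pool") x <- avgpool_forward(x)
      else {
        mp <- maxpool_forward(x)
        if (keep_cache) caches[[paste0("pool", l)]] <- mp
        x <- mp$out
      }
    }
    for (cn in c("_c1", "_c2")) x <- run_block(x, paste0("enc", l, cn))
    E[[l]] <- x
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    u <- upsample_nearest(x)
    u <- run_block(u, paste0("up", l))
    skip <- if (cfg$skip_mode == "dual_frame_subtraction") E[[l]] - u else E[[l]]
    x <- concat_channels(u, skip)
    for (cn in c("_c1", "_c2")) x <- run_block(x, paste0("dec", l, cn))
  }
  fin <- conv1_forward(x, params$final_W, params$final_b)
  if (keep_cache) caches$final <- fin
  list(S = fin$out, caches = caches, bn = bn)
}

# backward pass: dS -> gradients for every parameter
network_backward <- function(model, dS, caches) {
  cfg <- model$config
  params <- model$params
  grads <- list()
  fb <- conv1_backward(dS, caches$final, params$final_W)
  grads$final_W <- fb$dW
  grads$final_b <- fb$db
  dx <- fb$dX
  dE <- vector("list", cfg$depth)     # gradients flowing into encoder outputs
  for (l in seq_len(cfg$depth - 1L)) {
    for (cn in c("_c2", "_c1")) {
      nm <- paste0("dec", l, cn)
      bb <- block_backward(dx, caches[[nm]], params, nm, cfg, grads)
      grads <- bb$grads
      dx <- bb$dX
    }
    cu <- level_channels(cfg, l)
    du <- dx[, , seq_len(cu), , drop = FALSE]
    dskip <- dx[, , cu + seq_len(cu), , drop = FALSE]
    dE[[l]] <- dE[[l]] %+g% dskip
    if (cfg$skip_mode == "dual_frame_subtraction") du <- du - dskip
    nm <- paste0("up", l)
    bb <- block_backward(du, caches[[nm]], params, nm, cfg, grads)
    grads <- bb$grads
    dx <- downsample_sum(bb$dX)
    if (l == cfg$depth - 1L) dE[[cfg$depth]] <- dx
  }
  if (cfg$depth == 1L) dE[[1L]] <- dx
  # encoder, deepest level first
  dx <- dE[[cfg$depth]]
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) dx <- dx %+g% dE[[l]]
    for (cn in c("_c2", "_c1")) {
      nm <- paste0("enc", l, cn)
      bb <- block_backward(dx, caches[[nm]], params, nm, cfg, grads)
      grads <- bb$grads
      dx <- bb$dX
    }
    if (l > 1L) {
      dx <- if (cfg$downsample == "average_pool") avgpool_backward(dx)
            else maxpool_backward(dx, caches[[paste0("pool", l)]])
    }
  }
  grads
}

#' Run the separation network on an image batch
#'
#' Per-image forward pass (images are processed independently; only the
#' training loss couples a batch). Returns the predicted signed foreground
#' `S` and the background `L = D - S`, which satisfy `L + S = D` exactly.
#'
#' @param model a trained or freshly built `separation_model`.
#' @param D image batch (H x W x c x n, or anything [as_image_batch()]
#'   accepts); H and W must be divisible by `2^(depth - 1)`.
#' @return A [separation_tensors()] object.
#' @export
forward <- function(model, D) {
  stopifnot(inherits(model, "separation_model"))
  D <- check_batch(D)
  check_divisible(model, D)
  S <- network_forward(model, D)$S
  separation_tensors(D, S = S)
}

#' @export
predict.separation_model <- function(object, newdata, ...) {
  forward(object, newdata)
}
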