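#' Configuration of the synthetic cytology-image generator
#'
#' The generator emulates the structure that makes unsupervised separation
#' possible in liquid-based cytology: bright backgrounds shared across a
#' batch (nonnegative combinations of `background_rank` smooth basis
#' images, so the vectorized clean background stack has rank at most
#' `background_rank` per channel), sparse elliptical cells strictly darker
#' than the local background with a soft low-contrast rim, isolated
#' single-pixel debris, optional per-subject background tint
#' ("deterioration"), and Gaussian pixel noise added to the background
#' only, so the true foreground stays exactly sparse.
#'
#' @param n_images number of images in the batch.
#' @param height,width image size in pixels.
#' @param channels 1 (grayscale) or 3 (color).
#' @param background_rank number of smooth basis images, <= `n_images`.
#' @param cell_count_range integer range (lo, hi) of cells per image.
#' @param cell_radius_range range (lo, hi) of ellipse semi-axes in pixels.
#' @param cell_intensity_drop peak darkening of a cell below its local
#'   background, in pixel-value units.
#' @param edge_softness fraction of the cell radius over which the
#'   darkening fades to zero (the low-contrast cytoplasm rim).
#' @param debris_pixel_rate probability that a background pixel carries an
#'   isolated dark debris speck.
#' @param debris_drop darkening of a debris pixel.
#' @param noise_sd standard deviation of the Gaussian background noise
#'   (truncated at 4 sd so pixel values stay inside \[0, 1\]).
#' @param tint_strength per-subject background tint amplitude in \[0, 1\];
#'   0 disables tinting.
#' @param n_subjects number of subjects the images are split across.
#' @param nonsparse_fraction fraction of images packed with enough cells
#'   to cover more than half of the pixels.
#' @param seed integer seed; the generator is deterministic given the
#'   config.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_images = 48L, height = 64L, width = 64L,
                             channels = 1L, background_rank = 2L,
                             cell_count_range = c(1L, 4L),
                             cell_radius_range = c(5, 11),
                             cell_intensity_drop = 0.4,
                             edge_softness = 0.3,
                             debris_pixel_rate = 0.001,
                             debris_drop = 0.35,
                             noise_sd = 0.01,
                             tint_strength = 0,
                             n_subjects = 4L,
                             nonsparse_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_images = as.integer(n_images), height = as.integer(height),
              width = as.integer(width), channels = as.integer(channels),
              background_rank = as.integer(background_rank),
              cell_count_range = as.integer(round(cell_count_range)),
              cell_radius_range = as.numeric(cell_radius_range),
              cell_intensity_drop = cell_intensity_drop,
              edge_softness = edge_softness,
              debris_pixel_rate = debris_pixel_rate,
              debris_drop = debris_drop, noise_sd = noise_sd,
              tint_strength = tint_strength,
              n_subjects = as.integer(n_subjects),
              nonsparse_fraction = nonsparse_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_images < 1L || height < 2L || width < 2L) stop("degenerate geometry")
    if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
    if (background_rank < 1L || background_rank > n_images)
      stop("background_rank must be in [1, n_images]")
    if (any(cell_count_range < 0L) || cell_count_range[1L] > cell_count_range[2L])
      stop("invalid cell_count_range")
    if (cell_radius_range[2L] >= min(height, width) / 2)
      stop("cell radius exceeds the image")
    rates <- c(debris_pixel_rate, tint_strength, nonsparse_fraction)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (cell_intensity_drop < 0) stop("cell_intensity_drop must be nonnegative")
  })
  structure(cfg, class = "synthetic_config")
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's stream afterwards
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth basis image scaled into [0.6, 1]: low-frequency cosine sheet plus
# a few broad Gaussian blotches
smooth_basis_image <- function(H, W) {
  hh <- matrix(seq_len(H), H, W) / H
  ww <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  img <- 0.5 + 0.5 * cos(2 * pi * (runif(1) * hh + runif(1) * ww) +
                           runif(1, 0, 2 * pi))
  for (b in seq_len(3L)) {
    ch <- runif(1); cw <- runif(1); s <- runif(1, 0.15, 0.4)
    img <- img + runif(1, 0.3, 1) * exp(-((hh - ch)^2 + (ww - cw)^2) / (2 * s^2))
  }
  img <- img - min(img)
  0.6 + 0.4 * img / max(img)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# one elliptical cell with a soft rim: list(dev = H x W matrix <= 0,
# mask = logical H x W interior)
cell_stamp <- function(H, W, center, radii, angle, drop, edge) {
  hh <- matrix(seq_len(H), H, W) - center[1L]
  ww <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2L]
  u <- (cos(angle) * hh + sin(angle) * ww) / radii[1L]
  v <- (-sin(angle) * hh + cos(angle) * ww) / radii[2L]
  rho <- sqrt(u^2 + v^2)
  list(dev = -drop * smoothstep((1 - rho) / max(edge, 1e-6)), mask = rho < 1)
}

#' Generate a synthetic cytology batch with ground truth
#'
#' Deterministic given the config (including its seed). The additive
#' identity `D = L + S` holds exactly: `L` is the noisy background and `S`
#' collects cells and debris as signed (negative) deviations, clamped so
#' `D` stays in \[0, 1\]. Ground-truth masks mark cell pixels only — debris
#' is foreground for the separator but not a cell, which lets ablation
#' experiments count suppressed debris.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `"synthetic_batch"`: `D`, `S`, `L` (noisy
#'   background), `L_clean` (noise-free background whose per-channel
#'   vectorized stack has rank at most `background_rank`), `masks`
#'   (H x W x n binary, cells only), `subject_id` (integer per image),
#'   and `cfg`.
#' @export
generate_batch <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_private_seed(cfg$seed, {
    H <- cfg$height; W <- cfg$width; C <- cfg$channels; n <- cfg$n_images
    r <- cfg$background_rank

    basis <- replicate(r, smooth_basis_image(H, W), simplify = FALSE)
    subject_id <- sort(rep_len(seq_len(cfg$n_subjects), n))
    tint <- matrix(1, cfg$n_subjects, C)
    if (cfg$tint_strength > 0)
      tint[] <- 1 + cfg$tint_strength * runif(cfg$n_subjects * C, -0.35, 0)

    # weights on a scaled simplex keep each background a nonnegative
    # combination of the basis (rank <= r per channel) and inside
    # [0.6 * s, s] with s in [0.75, 0.95]
    L_clean <- array(0, c(H, W, C, n))
    for (j in seq_len(n)) {
      prop <- runif(r, 0.2, 1); prop <- prop / sum(prop)
      s <- runif(1, 0.75, 0.95)
      bg <- Reduce(`+`, Map(`*`, basis, s * prop))
      for (k in seq_len(C))
        L_clean[, , k, j] <- bg * tint[subject_id[j], k]
    }

    noise <- array(0, dim(L_clean))
    if (cfg$noise_sd > 0)
      noise[] <- pmin(pmax(rnorm(length(noise), 0, cfg$noise_sd),
                           -4 * cfg$noise_sd), 4 * cfg$noise_sd)
    L <- pmin(L_clean + noise, 1)

    masks <- array(0, c(H, W, n))
    dev <- array(0, c(H, W, n))        # channel-shared signed deviation
    n_nonsparse <- round(cfg$nonsparse_fraction * n)
    nonsparse <- seq_len(n) > (n - n_nonsparse)
    for (j in seq_len(n)) {
      mask_j <- matrix(FALSE, H, W)
      dev_j <- matrix(0, H, W)
      place_one <- function() {
        rad <- runif(2L, cfg$cell_radius_range[1L], cfg$cell_radius_range[2L])
        ctr <- c(runif(1, rad[1L], H - rad[1L]), runif(1, rad[2L], W - rad[2L]))
        st <- cell_stamp(H, W, ctr, rad, runif(1, 0, pi),
                         cfg$cell_intensity_drop, cfg$edge_softness)
        dev_j <<- pmin(dev_j, st$dev)  # overlaps take the deeper drop
        mask_j <<- mask_j | st$mask
      }
      if (nonsparse[j]) {
        tries <- 0L
        while (mean(mask_j) <= 0.55 && tries < 200L) { place_one(); tries <- tries + 1L }
      } else {
        k <- sample(cfg$cell_count_range[1L]:cfg$cell_count_range[2L], 1L)
        for (q in seq_len(k)) place_one()
      }
      dev[, , j] <- dev_j
      masks[, , j] <- mask_j + 0
    }

    # isolated debris: sampled off-cell pixels, thinned so no two specks
    # touch (8-neighborhood)
    if (cfg$debris_pixel_rate > 0) {
      for (j in seq_len(n)) {
        cand <- which(matrix(runif(H * W) < cfg$debris_pixel_rate, H, W) &
                        masks[, , j] == 0)
        taken <- matrix(FALSE, H, W)
        for (idx in cand) {
          h <- (idx - 1L) %% H + 1L; w <- (idx - 1L) %/% H + 1L
          nb <- expand.grid(h = max(1L, h - 1L):min(H, h + 1L),
                            w = max(1L, w - 1L):min(W, w + 1L))
          if (!any(taken[cbind(nb$h, nb$w)])) {
            taken[h, w] <- TRUE
            dev[h, w, j] <- dev[h, w, j] - cfg$debris_drop
          }
        }
      }
    }

    # expand the shared deviation to channels, clamp so D >= 0.01, derive S
    S <- array(0, c(H, W, C, n))
    for (k in seq_len(C)) S[, , k, ] <- dev
    S <- pmax(S, -(L - 0.01))
    D <- L + S

    structure(list(D = D, S = S, L = L, L_clean = L_clean, masks = masks,
                   subject_id = subject_id, cfg = cfg),
              class = "synthetic_batch")
  })
}

#' @export
print.synthetic_batch <- function(x, ...) {
  cat(sprintf(
    "synthetic_batch: %d images %d x %d (c=%d), background rank <= %d, %d subjects\n",
    x$cfg$n_images, x$cfg$height, x$cfg$width, x$cfg$channels,
    x$cfg$background_rank, x$cfg$n_subjects))
  invisible(x)
}

#' Two-class synthetic dataset with a controllable background bias
#'
#' Produces two classes whose cell statistics differ subtly (class 2 cells
#' are drawn ~10% larger) and whose per-subject background tints are drawn
#' from uniform distributions whose centers are pulled apart by
#' `bias_strength`: tint offsets are Uniform(center - w, center + w) with
#' the class centers separated by `2 * w * bias_strength`. At strength 0
#' the two tint distributions are identical; at strength 1 they are
#' disjoint, so a threshold on the tint separates the classes perfectly.
#' The Bayes accuracy of the tint mixture is `0.5 + bias_strength / 2`,
#' which Monte-Carlo experiments can check against a background-only
#' classifier.
#'
#' @param cfg a [synthetic_config()]; `n_images` is used per class.
#' @param bias_strength background-bias level in \[0, 1\].
#' @return A list of class `"biased_dataset"`: `D` (2n images), `labels`
#'   (1/2), `masks`, `tints` (per-image tint offset), `bayes_accuracy`,
#'   and the two underlying `synthetic_batch` objects.
#' @export
make_biased_dataset <- function(cfg, bias_strength) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.numeric(bias_strength) || length(bias_strength) != 1L ||
      bias_strength < 0 || bias_strength > 1)
    stop("bias_strength must lie in [0, 1]")
  w <- 0.05                              # half-width of each tint distribution
  centers <- c(-1, 1) * w * bias_strength
  with_private_seed(cfg$seed + 1000003L, {
    batches <- vector("list", 2L)
    tints <- vector("list", 2L)
    for (cls in 1:2) {
      sub_cfg <- cfg
      sub_cfg$seed <- cfg$seed + cls * 7919L
      sub_cfg$tint_strength <- 0
      if (cls == 2L) sub_cfg$cell_radius_range <- cfg$cell_radius_range * 1.1
      b <- generate_batch(sub_cfg)
      # apply the class tint multiplicatively per subject: offset t shifts
      # the background brightness by factor (1 + t)
      t_sub <- runif(sub_cfg$n_subjects, centers[cls] - w, centers[cls] + w)
      t_img <- t_sub[b$subject_id]
      for (j in seq_len(sub_cfg$n_images)) {
        f <- 1 + t_img[j]
        b$L[, , , j] <- b$L[, , , j] * f
        b$L_clean[, , , j] <- b$L_clean[, , , j] * f
        b$D[, , , j] <- b$L[, , , j] + b$S[, , , j]
      }
      b$D <- pmin(pmax(b$D, 0), 1)
      b$S <- b$D - b$L
      batches[[cls]] <- b
      tints[[cls]] <- t_img
    }
    H <- cfg$height; W <- cfg$width; C <- cfg$channels; n <- cfg$n_images
    D <- array(0, c(H, W, C, 2L * n))
    masks <- array(0, c(H, W, 2L * n))
    D[, , , seq_len(n)] <- batches[[1L]]$D
    D[, , , n + seq_len(n)] <- batches[[2L]]$D
    masks[, , seq_len(n)] <- batches[[1L]]$masks
    masks[, , n + seq_len(n)] <- batches[[2L]]$masks
    structure(list(D = D, labels = rep(1:2, each = n), masks = masks,
                   tints = c(tints[[1L]], tints[[2L]]),
                   bayes_accuracy = 0.5 + bias_strength / 2,
                   class_batches = batches),
              class = "biased_dataset")
  })
}
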