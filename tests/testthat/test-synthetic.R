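test_that("generation is deterministic and additively exact", {
  cfg <- synthetic_config(n_images = 6L, height = 24L, width = 20L, seed = 42L,
                          cell_radius_range = c(2.5, 5), tint_strength = 0.5,
                          n_subjects = 3L)
  b1 <- generate_batch(cfg)
  b2 <- generate_batch(cfg)
  expect_identical(b1$D, b2$D)
  expect_identical(b1$masks, b2$masks)
  # exact additivity, including clipping
  expect_identical(b1$D, b1$L + b1$S)
  expect_true(all(b1$D >= 0 & b1$D <= 1))
  # generating does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_batch(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("clean backgrounds have rank at most background_rank per channel", {
  for (r in c(1L, 3L)) {
    cfg <- synthetic_config(n_images = 10L, height = 24L, width = 24L,
                            background_rank = r, cell_count_range = c(0L, 0L),
                            cell_radius_range = c(3, 6),
                            debris_pixel_rate = 0, noise_sd = 0, seed = r)
    b <- generate_batch(cfg)
    expect_identical(b$S, array(0, dim(b$S)))
    sv <- svd(unfold_background(b$L_clean), nu = 0, nv = 0)$d
    expect_lt(sv[r + 1] / sv[1], 1e-10)
  }
  # channel-tinted color batch: certificate holds channel-wise
  cfgc <- synthetic_config(n_images = 8L, height = 16L, width = 16L,
                           channels = 3L, background_rank = 2L,
                           cell_count_range = c(0L, 0L),
                           cell_radius_range = c(2.5, 4),
                           debris_pixel_rate = 0,
                           noise_sd = 0, tint_strength = 1, seed = 5L)
  bc <- generate_batch(cfgc)
  for (k in 1:3) {
    ch <- bc$L_clean[, , k, , drop = FALSE]
    sv <- svd(unfold_background(ch), nu = 0, nv = 0)$d
    expect_lt(sv[3] / sv[1], 1e-10)
  }
})

test_that("cells are darker than the background and masks exclude debris", {
  cfg <- synthetic_config(n_images = 8L, height = 32L, width = 32L,
                          debris_pixel_rate = 0.002, seed = 12L,
                          cell_radius_range = c(3, 6))
  b <- generate_batch(cfg)
  expect_true(all(b$S <= 0))
  expect_true(all(b$S[, , 1, ][b$masks == 1] < 0))
  expect_true(all(b$D[b$masks == 1] <
                    b$L[, , 1, ][b$masks == 1]))
  # some foreground pixels lie outside the cell masks (the debris)
  fg_outside <- sum(b$S[, , 1, ] < 0 & b$masks == 0)
  expect_gt(fg_outside, 0)
  # debris specks are isolated single pixels: each stamps one pixel, so the
  # off-mask foreground area is far below any cell's area
  per_image_outside <- vapply(seq_len(8), function(j)
    sum(b$S[, , 1, j] < 0 & b$masks[, , j] == 0), 0)
  expect_lt(max(per_image_outside), 10)
})

test_that("mask coverage sits in the analytic expectation band", {
  cfg <- synthetic_config(n_images = 60L, height = 64L, width = 64L,
                          cell_count_range = c(1L, 4L),
                          cell_radius_range = c(5, 11),
                          debris_pixel_rate = 0, noise_sd = 0, seed = 77L)
  b <- generate_batch(cfg)
  frac <- mean(b$masks)
  # union bound: E[cells] * pi * E[r]^2 / (H * W); overlap and pixel
  # discretization pull the realized coverage below it
  upper <- mean(1:4) * pi * mean(c(5, 11))^2 / (64 * 64)
  expect_lt(frac, upper * 1.05)
  expect_gt(frac, upper * 0.7)
})

test_that("nonsparse images exceed half coverage when requested", {
  cfg <- synthetic_config(n_images = 4L, height = 32L, width = 32L,
                          cell_radius_range = c(4, 7),
                          nonsparse_fraction = 0.5, seed = 3L)
  b <- generate_batch(cfg)
  cover <- apply(b$masks, 3, mean)
  expect_true(all(cover[3:4] > 0.5))
  expect_true(all(cover[1:2] < 0.5))
})

test_that("background bias dial spans indistinguishable to separable", {
  cfg <- synthetic_config(n_images = 20L, height = 16L, width = 16L,
                          cell_radius_range = c(2.5, 4), n_subjects = 10L,
                          seed = 21L)
  # strength 0: identical generating parameters -> stated Bayes rate 1/2
  d0 <- make_biased_dataset(cfg, 0)
  expect_identical(d0$bayes_accuracy, 0.5)
  # strength 1: tints fully separable by a threshold
  d1 <- make_biased_dataset(cfg, 1)
  expect_identical(d1$bayes_accuracy, 1)
  thr <- (max(d1$tints[d1$labels == 1]) + min(d1$tints[d1$labels == 2])) / 2
  expect_lte(max(d1$tints[d1$labels == 1]), min(d1$tints[d1$labels == 2]))
  acc <- mean((d1$tints > thr) + 1 == d1$labels)
  expect_identical(acc, 1)
  expect_identical(dim(d1$D)[4], 40L)
  expect_identical(d1$D, with(d1, {
    out <- array(0, dim(D))
    out[, , , 1:20] <- class_batches[[1]]$D
    out[, , , 21:40] <- class_batches[[2]]$D
    out
  }))
  expect_error(make_biased_dataset(cfg, 1.2), "bias_strength")
})

test_that("tint-threshold classifier attains the analytic Bayes rate", {
  # Monte-Carlo over many subjects at intermediate strength: the optimal
  # tint threshold (midpoint of the class centers) classifies at the
  # closed-form Bayes accuracy 1/2 + s/2 of the uniform tint mixture
  cfg <- synthetic_config(n_images = 300L, height = 4L, width = 4L,
                          cell_count_range = c(0L, 0L),
                          cell_radius_range = c(1, 1.4),
                          debris_pixel_rate = 0, n_subjects = 300L, seed = 8L)
  s <- 0.5
  d <- make_biased_dataset(cfg, s)
  acc <- mean((d$tints > 0) + 1 == d$labels)
  expect_equal(acc, 0.5 + s / 2, tolerance = 0.06)
})
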