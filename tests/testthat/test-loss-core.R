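test_that("unfoldings follow the documented vectorization layout", {
  # single image: one column equal to the vectorized image
  x1 <- rand_batch(3, 4, 1, 1, seed = 2)
  expect_equal(dim(unfold_background(x1)), c(12L, 1L))
  expect_equal(unfold_background(x1), oracle_unfold_background(x1))

  # all-zero 2-image batch
  z <- array(0, c(2, 2, 1, 2))
  expect_identical(unfold_background(z), matrix(0, 4, 2))

  # distinct entries, multi-channel: index-by-index oracle
  x <- array(as.numeric(1:12), c(2, 2, 3, 1))
  expect_equal(unfold_background(x), oracle_unfold_background(x))
  expect_equal(unfold_foreground_channels(x), oracle_unfold_foreground(x))

  x2 <- rand_batch(4, 3, 3, 2, seed = 5)
  expect_equal(unfold_background(x2), oracle_unfold_background(x2))
  expect_equal(unfold_foreground_channels(x2), oracle_unfold_foreground(x2))

  # c = 1 foreground unfolding is a single row of all pixels
  expect_equal(dim(unfold_foreground_channels(x1)), c(1L, 12L))

  # shape errors
  expect_error(unfold_background(array(0, c(1, 3, 1, 1))), "at least 2 x 2")
  expect_error(unfold_background(array(0, c(3, 3, 2, 1))), "channel")
})

test_that("unfoldings round-trip bit-exactly", {
  for (seed in 1:3) {
    x <- rand_batch(6, 5, sample(c(1, 3), 1), 4, seed = seed, signed = TRUE)
    d <- dim(x)
    expect_identical(fold_background(unfold_background(x), d[1], d[2], d[3]), x)
    expect_identical(
      fold_foreground_channels(unfold_foreground_channels(x), d[1], d[2]), x)
  }
})

test_that("foreground channel images reproduce the batch and its layout", {
  x <- rand_batch(3, 3, 3, 2, seed = 9, signed = TRUE)
  imgs <- foreground_as_channel_images(x)
  expect_length(imgs, 6L)
  # image-major, channel-minor ordering; values verified per pixel
  i <- 0L
  for (j in 1:2) for (k in 1:3) {
    i <- i + 1L
    for (h in 1:3) for (w in 1:3) expect_identical(imgs[[i]][h, w], x[h, w, k, j])
  }
  # round trip
  back <- array(0, dim(x))
  i <- 0L
  for (j in 1:2) for (k in 1:3) { i <- i + 1L; back[, , k, j] <- imgs[[i]] }
  expect_identical(back, x)
  # n = 1, c = 1 is the identity
  one <- rand_batch(4, 4, 1, 1)
  expect_identical(foreground_as_channel_images(one)[[1]], one[, , 1, 1])
})

test_that("nuclear norm matches an independent oracle and its invariants", {
  expect_equal(nuclear_norm(diag(3)), 3)
  expect_equal(nuclear_norm(diag(c(3, 4))), 7)
  for (seed in 1:10) {
    M <- withr::with_seed(seed, matrix(rnorm(20), 5, 4))
    expect_equal(nuclear_norm(M), oracle_nuclear(M), tolerance = 1e-10)
    expect_equal(nuclear_norm(M), nuclear_norm(t(M)), tolerance = 1e-12)
    # spectral <= nuclear <= sqrt(rank) * Frobenius
    spectral <- svd(M, nu = 0, nv = 0)$d[1]
    expect_gte(nuclear_norm(M), spectral - 1e-12)
    expect_lte(nuclear_norm(M), sqrt(4) * sqrt(sum(M^2)) + 1e-12)
  }
  expect_error(nuclear_norm(matrix(c(1, NA), 1)), "non-finite|numeric")
})

test_that("l2,1 norm sums columnwise Euclidean norms", {
  expect_identical(l21_norm(matrix(0, 3, 4)), 0)
  # a single row reduces to the l1 norm
  expect_identical(l21_norm(matrix(c(1, -2, 3), 1)), 6)
  expect_identical(l21_norm(cbind(c(3, 4), c(0, 0))), 5)
  for (seed in 1:5) {
    M <- withr::with_seed(seed, matrix(rnorm(3 * 17), 3))
    expect_equal(l21_norm(M), oracle_l21(M), tolerance = 1e-12)
    expect_equal(l21_norm(M[1, , drop = FALSE]), sum(abs(M[1, ])),
                 tolerance = 1e-12)
  }
})

test_that("anisotropic TV implements the literal index range", {
  expect_identical(anisotropic_tv(matrix(5, 4, 7)), 0)
  expect_identical(anisotropic_tv(matrix(c(0, 1, 1, 0), 2, 2)), 2)
  for (seed in 1:10) {
    img <- withr::with_seed(seed, matrix(rnorm(30), 6, 5))
    expect_equal(anisotropic_tv(img), oracle_tv(img), tolerance = 1e-12)
    expect_equal(anisotropic_tv(img, full_boundary = TRUE),
                 oracle_tv(img, full_boundary = TRUE), tolerance = 1e-12)
    # intensity-shift invariance
    expect_equal(anisotropic_tv(img + 3.7), anisotropic_tv(img),
                 tolerance = 1e-10)
  }
  # the literal range ignores the last row/column differences
  img <- matrix(0, 3, 3); img[3, 3] <- 1
  expect_identical(anisotropic_tv(img), 0)
  expect_identical(anisotropic_tv(img, full_boundary = TRUE), 2)
  expect_error(anisotropic_tv(matrix(1, 1, 5)), "H >= 2")
})

test_that("separation loss composes its three terms", {
  # S = 0 and rank-1 L: loss is the single singular value
  withr::with_seed(4, {
    u <- rnorm(12); v <- rnorm(3)
  })
  L <- fold_background(tcrossprod(u, v), 4, 3, 1)
  st <- separation_tensors(D = L, S = array(0, dim(L)))
  sigma <- sqrt(sum(u^2)) * sqrt(sum(v^2))
  expect_equal(separation_loss(st, loss_config(0.5, 7)), sigma,
               tolerance = 1e-10)

  # term-by-term oracle on random tensors
  for (seed in 1:5) {
    S <- rand_batch(6, 5, 3, 4, seed = seed, signed = TRUE)
    D <- clip01(rand_batch(6, 5, 3, 4, seed = seed + 50))
    st <- separation_tensors(D, S = S)
    expected <- oracle_nuclear(oracle_unfold_background(D - S)) +
      0.01 * oracle_l21(oracle_unfold_foreground(S)) +
      0.005 * sum(vapply(foreground_as_channel_images(S), oracle_tv, 0))
    expect_equal(separation_loss(st, loss_config(0.01, 0.005)), expected,
                 tolerance = 1e-10)
  }
})

test_that("single-channel zero-TV loss equals the RPCA objective", {
  for (seed in 1:20) {
    S <- rand_batch(5, 4, 1, 3, seed = seed, signed = TRUE)
    D <- clip01(rand_batch(5, 4, 1, 3, seed = seed + 100))
    st <- separation_tensors(D, S = S)
    lam <- withr::with_seed(seed, runif(1, 0.001, 1))
    lhs <- separation_loss(st, loss_config(lam, 0))
    rhs <- rpca_objective(unfold_background(st$L),
                          unfold_foreground_channels(st$S), lam)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("rpca objective matches independent norms", {
  expect_identical(rpca_objective(matrix(0, 2, 2), matrix(0, 2, 2), 1), 0)
  expect_equal(rpca_objective(diag(c(2, 2)), matrix(0, 2, 2), 1), 4)
  for (seed in 1:5) {
    L <- withr::with_seed(seed, matrix(rnorm(12), 3))
    S <- withr::with_seed(seed + 9, matrix(rnorm(12), 3))
    expect_equal(rpca_objective(L, S, 0.3),
                 oracle_nuclear(L) + 0.3 * sum(abs(S)), tolerance = 1e-8)
  }
})

test_that("default sparsity weight is 1/sqrt(max(m, n))", {
  expect_equal(default_lambda(81920, 32), 3.49e-3, tolerance = 2e-3)
  expect_equal(signif(default_lambda(81920, 81920), 3), 3.49e-3)
  expect_identical(default_lambda(1, 1), 1)
  expect_identical(default_lambda(262144, 135), 1 / 512)
  expect_error(default_lambda(0, 3), "positive")
  expect_error(default_lambda(10, -1), "positive")
})

test_that("loss terms are nonnegative and vanish only in the degenerate case", {
  # constructed case: L = 0 and S constant (zero under the literal TV range)
  S <- array(0.3, c(4, 4, 1, 2))
  st <- separation_tensors(D = S, S = S)   # L = 0
  cfg <- loss_config(0, 1)
  expect_identical(separation_loss(st, cfg), 0)
  # any nonzero L makes it positive
  st2 <- separation_tensors(D = S, S = S * 0)
  expect_gt(separation_loss(st2, cfg), 0)
})
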