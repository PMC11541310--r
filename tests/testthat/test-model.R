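test_that("initialization is deterministic and counted in closed form", {
  cfg <- network_config(depth = 2L, base_channels = 4L, in_channels = 1L)
  m1 <- build_network(cfg, seed = 10L)
  m2 <- build_network(cfg, seed = 10L)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(cfg, seed = 11L)
  expect_false(identical(m1$params, m3$params))

  # hand-derived parameter count for depth 2, base 4, c = 1, with
  # per-channel scale-and-shift normalization parameters:
  # enc1: conv(1->4) 9*1*4+4, conv(4->4) 9*4*4+4, norm 2*(4+4)
  # enc2: conv(4->8) 9*4*8+8, conv(8->8) 9*8*8+8, norm 2*(8+8)
  # up1:  conv(8->4) 9*8*4+4, norm 2*4
  # dec1: conv(8->4) 9*8*4+4, conv(4->4) 9*4*4+4, norm 2*(4+4)
  # final: 1x1 conv(4->1) 4+1
  expected <- (36 + 4) + (144 + 4) + 16 +
    (288 + 8) + (576 + 8) + 32 +
    (288 + 4) + 8 +
    (288 + 4) + (144 + 4) + 16 +
    5
  expect_identical(n_parameters(m1), as.integer(expected))
})

test_that("forward preserves shape and the additivity identity exactly", {
  for (cfg in list(network_config(depth = 1L, base_channels = 3L),
                   network_config(depth = 3L, base_channels = 4L),
                   network_config(depth = 2L, base_channels = 4L,
                                  in_channels = 3L,
                                  skip_mode = "concatenation"))) {
    model <- build_network(cfg, seed = 2L)
    model$params$final_W[] <- withr::with_seed(3, rnorm(length(model$params$final_W), 0, 0.1))
    D <- rand_batch(8, 12, cfg$in_channels, 2, seed = 6)
    st <- forward(model, D)
    expect_identical(dim(st$S), dim(D))
    expect_identical(st$L, st$D - st$S)         # exact, not approximate
    # determinism of the forward pass
    expect_identical(forward(model, D)$S, st$S)
  }
})

test_that("zero-initialized final layer gives S = 0, L = D", {
  model <- build_network(network_config(depth = 2L, base_channels = 4L),
                         seed = 1L)   # final_init = "zero" default
  D <- rand_batch(8, 8, 1, 3, seed = 4)
  st <- forward(model, D)
  expect_identical(st$S, array(0, dim(D)))
  expect_identical(st$L, D)
})

test_that("indivisible image sizes are rejected with the required divisor", {
  model <- build_network(network_config(depth = 3L, base_channels = 4L), 1L)
  expect_error(forward(model, rand_batch(10, 8, 1, 1)), "divisible by 4")
  expect_error(forward(model, rand_batch(8, 8, 3, 1)), "channels")
  # depth 1 accepts any size
  m1 <- build_network(network_config(depth = 1L, base_channels = 3L), 1L)
  expect_identical(dim(forward(m1, rand_batch(5, 7, 1, 2))$S), c(5L, 7L, 1L, 2L))
})

test_that("a fully convolutional model is translation covariant inside borders", {
  cfg <- network_config(depth = 1L, base_channels = 6L, final_init = "random")
  model <- build_network(cfg, seed = 9L)
  D <- rand_batch(20, 20, 1, 1, seed = 12)
  # shift the input by 3 pixels in h and w (content moves, borders refill)
  Ds <- array(0, dim(D))
  Ds[4:20, 4:20, 1, 1] <- D[1:17, 1:17, 1, 1]
  S <- forward(model, D)$S
  Ss <- forward(model, Ds)$S
  # compare away from all borders with a generous margin for the receptive field
  margin <- 6
  inner <- (margin + 1):(17 - margin)
  expect_equal(Ss[inner + 3, inner + 3, 1, 1], S[inner, inner, 1, 1],
               tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  # leaky nonlinearity keeps the finite-difference probe away from the
  # ReLU kink, making the check sharp
  cfg <- network_config(depth = 2L, base_channels = 3L, in_channels = 1L,
                        nonlinearity = "leaky_relu", final_init = "random")
  model <- build_network(cfg, seed = 15L)
  D <- rand_batch(8, 8, 1, 2, seed = 16)
  lcfg <- loss_config(0.02, 0.01)
  fwd <- cytosep:::network_forward(model, D, keep_cache = TRUE, training = TRUE)
  lg <- cytosep:::separation_loss_value_grad(D, fwd$S, lcfg)
  grads <- cytosep:::network_backward(model, lg$grad, fwd$caches)
  loss_at <- function(params) {
    m <- model; m$params <- params
    f <- cytosep:::network_forward(m, D, training = TRUE)
    cytosep:::separation_loss_value_grad(D, f$S, lcfg)$value
  }
  eps <- 1e-6
  withr::with_seed(20, {
    for (nm in names(model$params)) {
      for (i in sample(length(model$params[[nm]]),
                       min(3, length(model$params[[nm]])))) {
        pp <- model$params
        pp[[nm]][i] <- pp[[nm]][i] + eps
        f1 <- loss_at(pp)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        f0 <- loss_at(pp)
        num <- (f1 - f0) / (2 * eps)
        # conv biases feeding batch norm are null directions (the mean is
        # subtracted); compare those on an absolute scale
        if (grepl("_b$", nm) && nm != "final_b")
          expect_lt(abs(grads[[nm]][i] - num), 1e-6)
        else
          expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                       label = paste("gradient of", nm))
      }
    }
  })
})

test_that("convolution layer matches a direct sliding-window oracle", {
  withr::with_seed(30, {
    X <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
    Wm <- matrix(rnorm(3 * 18, 0, 0.5), 3, 18)
    b <- rnorm(3)
  })
  out <- cytosep:::conv3_forward(X, Wm, b)$out
  # oracle: explicit loops over output position, offset and channel
  oracle <- array(0, c(6, 5, 3, 2))
  for (n in 1:2) for (co in 1:3) for (h in 1:6) for (w in 1:5) {
    acc <- b[co]
    for (o in 1:9) {
      dh <- (o - 1) %% 3 - 1; dw <- (o - 1) %/% 3 - 1
      hh <- h + dh; ww <- w + dw
      if (hh >= 1 && hh <= 6 && ww >= 1 && ww <= 5)
        for (ci in 1:2)
          acc <- acc + Wm[co, (o - 1) * 2 + ci] * X[hh, ww, ci, n]
    }
    oracle[h, w, co, n] <- acc
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})
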