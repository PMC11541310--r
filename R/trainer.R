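#' Training configuration for unsupervised separation
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' `1e-3`, mini-batches of 32 images, 30 epochs. The batch size must be at
#' least 2 because the nuclear-norm term degenerates to the Frobenius norm
#' of a single column for one image. Adam's betas/epsilon are the
#' conventional (0.9, 0.999, 1e-8).
#'
#' @param batch_size mini-batch size n (>= 2).
#' @param learning_rate Adam step size.
#' @param lr_decay multiplicative per-epoch decay of the learning rate
#'   (1 = constant). A mild decay (e.g. 0.95) settles the delicate
#'   sparse/low-rank equilibrium once the separation has locked in.
#' @param grad_clip cap on the global l2 norm of the parameter gradient
#'   per step (`Inf` disables). Clipping tames the occasional large
#'   nuclear-norm subgradients that otherwise destabilize small batches.
#' @param epochs number of passes over the training set.
#' @param lambda_sparse sparsity weight; `NULL` means `default_lambda(c*m,
#'   batch_size)` of the training images (the RPCA rule). With a large TV
#'   weight a smaller value can be set explicitly, since TV also
#'   penalizes the foreground.
#' @param lambda_tv total-variation weight.
#' @param tv_full_boundary see [loss_config()].
#' @param seed integer; controls initialization and batch shuffling.
#' @param selection_metric `"auto"` (validation loss without masks,
#'   validation Dice with), `"validation_loss"`, or `"validation_dsc"`.
#' @param selection_every evaluate the selection metric every this many
#'   gradient steps in addition to every epoch end (`NULL` = epoch ends
#'   only). At desk scale an epoch is only a few steps and the
#'   sparse/low-rank equilibrium makes trajectories oscillate, so finer
#'   checkpointing recovers good transient models.
#' @param reshuffle `"epoch"` draws a fresh seeded batch composition every
#'   epoch (the reference protocol); `"once"` shuffles once and keeps the
#'   batch composition fixed.
#' @param restarts number of independent training runs (different seeded
#'   initializations and shuffles); the model best by the selection
#'   metric across all runs is returned; `epochs` is the per-restart
#'   count.
#' @param ema_decay if non-`NULL`, maintain an exponential moving average
#'   of the parameters (per-step decay, e.g. 0.95) and evaluate it as an
#'   additional model-selection candidate at each epoch end. Tail
#'   averaging often sits closer to the center of the oscillation the
#'   sparse/low-rank equilibrium induces than any single iterate.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         lr_decay = 1, grad_clip = Inf, epochs = 30L,
                         lambda_sparse = NULL, lambda_tv = 0,
                         tv_full_boundary = FALSE, seed = 1L,
                         selection_metric = c("auto", "validation_loss",
                                              "validation_dsc"),
                         selection_every = NULL,
                         reshuffle = c("epoch", "once"),
                         restarts = 1L, ema_decay = NULL) {
  if (restarts < 1L) stop("restarts must be >= 1")
  if (!is.null(ema_decay) && (ema_decay <= 0 || ema_decay >= 1))
    stop("ema_decay must be in (0, 1)")
  if (!is.null(selection_every) && selection_every < 1) stop("selection_every must be >= 1")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (!is.numeric(grad_clip) || grad_clip <= 0) stop("grad_clip must be positive")
  batch_size <- as.integer(batch_size)
  if (batch_size < 2L) stop("batch_size must be >= 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (!is.null(lambda_sparse) && lambda_sparse < 0) stop("lambda_sparse must be >= 0")
  if (lambda_tv < 0) stop("lambda_tv must be >= 0")
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 lr_decay = lr_decay, grad_clip = grad_clip,
                 epochs = as.integer(epochs), lambda_sparse = lambda_sparse,
                 lambda_tv = lambda_tv,
                 tv_full_boundary = isTRUE(tv_full_boundary),
                 seed = as.integer(seed),
                 selection_metric = match.arg(selection_metric),
                 selection_every = if (is.null(selection_every)) NULL
                                   else as.integer(selection_every),
                 reshuffle = match.arg(reshuffle),
                 restarts = as.integer(restarts), ema_decay = ema_decay),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# split shuffled indices into batches; singleton remainders are folded into
# the previous batch (the nuclear-norm term needs n >= 2)
make_batches <- function(idx, batch_size) {
  ends <- seq(0L, length(idx), by = batch_size)
  if (ends[length(ends)] < length(idx)) ends <- c(ends, length(idx))
  out <- list()
  for (i in seq_len(length(ends) - 1L))
    out[[i]] <- idx[(ends[i] + 1L):ends[i + 1L]]
  k <- length(out)
  if (k > 1L && length(out[[k]]) < 2L) {
    out[[k - 1L]] <- c(out[[k - 1L]], out[[k]])
    out[[k]] <- NULL
  }
  out
}

#' Train the separation network without annotation
#'
#' Minimizes the batch separation loss (nuclear norm of the unfolded
#' background + l2,1 sparsity + anisotropic TV of the foreground) over the
#' trainable parameters with Adam. Batch composition is a seeded shuffle
#' per epoch; the loss couples images within a batch through its
#' nuclear-norm term. After each epoch the model is scored on fixed,
#' seeded validation batches of the training batch size (the nuclear norm
#' is batch-size dependent, so a fixed grouping keeps epochs comparable);
#' the best epoch by the selection metric is returned.
#'
#' @param train_images training batch (H x W x c x n_train).
#' @param val_images validation batch (>= 1 image, same geometry).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param val_masks optional H x W x n_val ground-truth cell masks; when
#'   supplied, per-epoch validation Dice (with per-epoch threshold
#'   selection) is recorded and used for model selection under the
#'   `"auto"` metric.
#' @param verbose print per-epoch losses.
#' @return An object of class `"cytosep_fit"`: list with `model` (the
#'   selected `separation_model`), `history` (tibble: epoch, train_loss,
#'   val_loss, val_dsc, val_tau), `best_epoch`, `loss_config`,
#'   `train_config`.
#' @export
train <- function(train_images, val_images, net_cfg, train_cfg,
                  val_masks = NULL, verbose = FALSE) {
  stopifnot(inherits(net_cfg, "network_config"), inherits(train_cfg, "train_config"))
  runs <- vector("list", train_cfg$restarts)
  for (r in seq_len(train_cfg$restarts)) {
    cfg_r <- train_cfg
    cfg_r$seed <- train_cfg$seed + 7919L * (r - 1L)
    if (verbose && train_cfg$restarts > 1L) message("restart ", r)
    runs[[r]] <- train_single_run(train_images, val_images, net_cfg, cfg_r,
                                  val_masks = val_masks, verbose = verbose)
  }
  scores <- vapply(runs, function(x) x$best_score, numeric(1L))
  best <- which.min(scores)
  fit <- runs[[best]]
  fit$history <- do.call(rbind, lapply(seq_along(runs), function(r)
    tibble::add_column(runs[[r]]$history, restart = r, .before = 1L)))
  fit$best_restart <- best
  fit$train_config <- train_cfg
  fit
}

train_single_run <- function(train_images, val_images, net_cfg, train_cfg,
                             val_masks = NULL, verbose = FALSE) {
  train_images <- check_batch(train_images, "training images")
  val_images <- check_batch(val_images, "validation images")
  d <- batch_dims(train_images)
  dv <- batch_dims(val_images)
  if (!identical(dim(train_images)[1:3], dim(val_images)[1:3]))
    stop("training and validation images must share (H, W, c)")
  if (d$n < train_cfg$batch_size)
    stop(sprintf("need at least batch_size = %d training images, got %d",
                 train_cfg$batch_size, d$n))

  lam <- train_cfg$lambda_sparse
  if (is.null(lam)) lam <- default_lambda(d$c * d$m, train_cfg$batch_size)
  lcfg <- loss_config(lam, train_cfg$lambda_tv, train_cfg$tv_full_boundary)

  metric <- train_cfg$selection_metric
  if (metric == "auto")
    metric <- if (is.null(val_masks)) "validation_loss" else "validation_dsc"
  if (metric == "validation_dsc" && is.null(val_masks))
    stop("validation_dsc selection requires val_masks")

  model <- build_network(net_cfg, seed = train_cfg$seed)
  check_divisible(model, train_images)
  opt <- adam_init(model$params)

  with_private_seed(train_cfg$seed + 1L, {
    val_batches <- make_batches(sample.int(dv$n), train_cfg$batch_size)

    evaluate_val <- function() {
      val_loss <- 0
      for (b in val_batches) {
        Vb <- val_images[, , , b, drop = FALSE]
        Sv <- network_forward(model, Vb)$S
        val_loss <- val_loss +
          separation_loss(separation_tensors(Vb, S = Sv), lcfg)
      }
      val_dsc <- NA_real_; val_tau <- NA_real_
      if (!is.null(val_masks)) {
        Sv_all <- network_forward(model, val_images)$S
        sel <- select_threshold(Sv_all, val_masks)
        val_dsc <- sel$dice; val_tau <- sel$tau
      }
      list(loss = val_loss, dsc = val_dsc, tau = val_tau,
           score = if (metric == "validation_dsc") -val_dsc else val_loss)
    }

    # cheaper screen used at sub-epoch checkpoints: coarse threshold grid,
    # Dice metric only (validation loss is already cheap)
    coarse_grid <- exp(seq(log(1e-5), log(0.5), length.out = 50))
    evaluate_checkpoint <- function() {
      if (metric == "validation_dsc") {
        Sv_all <- network_forward(model, val_images)$S
        -select_threshold(Sv_all, val_masks, grid = coarse_grid)$dice
      } else {
        evaluate_val()$score
      }
    }

    history <- vector("list", train_cfg$epochs)
    best_score <- Inf
    best_params <- model$params
    best_bn <- model$bn
    best_epoch <- 0L
    step <- 0L
    ema <- if (!is.null(train_cfg$ema_decay)) model$params else NULL
    fixed_batches <- if (train_cfg$reshuffle == "once")
      make_batches(sample.int(d$n), train_cfg$batch_size) else NULL

    for (epoch in seq_len(train_cfg$epochs)) {
      lr_epoch <- train_cfg$learning_rate * train_cfg$lr_decay^(epoch - 1L)
      batches <- if (is.null(fixed_batches))
        make_batches(sample.int(d$n), train_cfg$batch_size) else fixed_batches
      epoch_loss <- 0
      for (b in batches) {
        Db <- train_images[, , , b, drop = FALSE]
        fwd <- network_forward(model, Db, keep_cache = TRUE, training = TRUE)
        lg <- separation_loss_value_grad(Db, fwd$S, lcfg)
        if (!is.finite(lg$value)) {
          bad <- names(lg$terms)[!is.finite(lg$terms)]
          stop("training aborted: non-finite loss (offending term: ",
               paste(if (length(bad)) bad else "gradient", collapse = ", "), ")")
        }
        epoch_loss <- epoch_loss + lg$value
        grads <- network_backward(model, lg$grad, fwd$caches)
        if (is.finite(train_cfg$grad_clip)) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
          if (gn > train_cfg$grad_clip) {
            sc <- train_cfg$grad_clip / gn
            grads <- lapply(grads, function(g) g * sc)
          }
        }
        st <- adam_step(model$params, grads, opt, lr_epoch)
        model$params <- st$params
        model$bn <- fwd$bn
        opt <- st$state
        step <- step + 1L
        if (!is.null(ema)) {
          bd <- train_cfg$ema_decay
          for (nm in names(ema))
            ema[[nm]] <- bd * ema[[nm]] + (1 - bd) * model$params[[nm]]
        }
        if (!is.null(train_cfg$selection_every) &&
            step %% train_cfg$selection_every == 0L) {
          sc <- evaluate_checkpoint()
          if (sc < best_score) {
            best_score <- sc
            best_params <- model$params
            best_bn <- model$bn
            best_epoch <- epoch
          }
        }
      }

      ev <- evaluate_val()
      if (ev$score < best_score) {
        best_score <- ev$score
        best_params <- model$params
        best_bn <- model$bn
        best_epoch <- epoch
      }
      if (!is.null(ema)) {
        cur <- model$params
        model$params <- ema
        sc_ema <- evaluate_checkpoint()
        if (sc_ema < best_score) {
          best_score <- sc_ema
          best_params <- ema
          best_bn <- model$bn
          best_epoch <- epoch
        }
        model$params <- cur
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss, val_loss = ev$loss,
        val_dsc = ev$dsc, val_tau = ev$tau)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch, epoch_loss,
                        ev$loss,
                        if (is.na(ev$dsc)) "" else sprintf("  dsc %.3f", ev$dsc)))
    }

    model$params <- best_params
    model$bn <- best_bn
    structure(list(model = model,
                   history = tibble::as_tibble(do.call(rbind, history)),
                   best_epoch = best_epoch, best_score = best_score,
                   loss_config = lcfg,
                   train_config = train_cfg, selection_metric = metric),
              class = "cytosep_fit")
  })
}

#' @export
print.cytosep_fit <- function(x, ...) {
  cat(sprintf(
    "cytosep_fit: %d restart(s) x %d epochs, best epoch %d of restart %d by %s\n",
    x$train_config$restarts, max(x$history$epoch), x$best_epoch,
    x$best_restart %||% 1L, x$selection_metric))
  invisible(x)
}

#' @export
predict.cytosep_fit <- function(object, newdata, ...) {
  forward(object$model, newdata)
}

#' Tidiers for cytosep fitted objects
#'
#' `tidy()` on a training fit returns the per-epoch history;
#' `glance()` returns a one-row summary. For RPCA results `glance()`
#' reports convergence and decomposition statistics.
#'
#' @param x a `cytosep_fit` or `rpca_result` object.
#' @param ... unused.
#' @return A tibble.
#' @name tidy_cytosep
NULL

#' @rdname tidy_cytosep
#' @method tidy cytosep_fit
#' @export
tidy.cytosep_fit <- function(x, ...) x$history

#' @rdname tidy_cytosep
#' @method glance cytosep_fit
#' @export
glance.cytosep_fit <- function(x, ...) {
  h <- x$history
  if (!is.null(h$restart)) h <- h[h$restart == (x$best_restart %||% 1L), ]
  tibble::tibble(epochs = max(h$epoch), restarts = x$train_config$restarts,
                 best_epoch = x$best_epoch,
                 train_loss = h$train_loss[nrow(h)],
                 best_val_loss = h$val_loss[x$best_epoch],
                 best_val_dsc = h$val_dsc[x$best_epoch],
                 lambda_sparse = x$loss_config$lambda_sparse,
                 lambda_tv = x$loss_config$lambda_tv,
                 parameters = n_parameters(x$model))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
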