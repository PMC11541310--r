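#' Plot training history
#'
#' Training and validation loss per epoch on a log scale, with the
#' selected epoch marked.
#'
#' @param object a `cytosep_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cytosep_fit
#' @export
autoplot.cytosep_fit <- function(object, ...) {
  h <- object$history
  if (!is.null(h$restart))
    h <- h[h$restart == (object$best_restart %||% 1L), ]
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_loss, set = "training"),
    data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "batch separation loss", colour = NULL,
                  title = "Unsupervised separation training") +
    ggplot2::theme_minimal()
}

#' Plot the threshold-selection Dice profile
#'
#' Mean validation Dice against the binarization threshold (log axis),
#' with the selected threshold marked.
#'
#' @param selection result of [select_threshold()].
#' @return A ggplot object.
#' @export
plot_threshold_profile <- function(selection) {
  ggplot2::ggplot(selection$profile,
                  ggplot2::aes(x = .data$tau, y = .data$mean_dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = selection$tau, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "binarization threshold", y = "mean Dice",
                  title = "Threshold selection") +
    ggplot2::theme_minimal()
}

#' Montage of images, predicted foregrounds and masks
#'
#' Tiles up to `max_images` columns: input, foreground visualization
#' (S + 0.8), and mask rows, as a raster plot.
#'
#' @param tensors a [separation_tensors()] object.
#' @param masks optional H x W x n binary masks.
#' @param max_images number of images to show.
#' @return A ggplot object.
#' @export
plot_separation <- function(tensors, masks = NULL, max_images = 6L) {
  stopifnot(inherits(tensors, "separation_tensors"))
  d <- batch_dims(tensors$D)
  n <- min(d$n, max_images)
  rows <- list(input = tensors$D, foreground = clip01(tensors$S + 0.8))
  to_df <- function(arr4, label, j) {
    img <- if (d$c == 1L) arr4[, , 1L, j] else
      0.299 * arr4[, , 1L, j] + 0.587 * arr4[, , 2L, j] + 0.114 * arr4[, , 3L, j]
    data.frame(h = rep(seq_len(d$H), d$W), w = rep(seq_len(d$W), each = d$H),
               value = as.vector(img), row = label, image = j)
  }
  df <- do.call(rbind, unlist(lapply(seq_len(n), function(j) {
    out <- list(to_df(rows$input, "input", j), to_df(rows$foreground, "S + 0.8", j))
    if (!is.null(masks))
      out <- c(out, list(data.frame(h = rep(seq_len(d$H), d$W),
                                    w = rep(seq_len(d$W), each = d$H),
                                    value = as.vector(masks[, , j] + 0),
                                    row = "mask", image = j)))
    out
  }), recursive = FALSE))
  df$row <- factor(df$row, levels = c("input", "S + 0.8", "mask"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$h,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::facet_grid(row ~ image) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
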