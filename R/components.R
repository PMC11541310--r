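#' Label and count connected components of a binary mask
#'
#' 8-connected component labeling by flood fill, used to analyze predicted
#' masks — e.g. counting spurious components that do not touch any true
#' cell pixel in the total-variation ablation.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @return `label_components()`: an integer matrix of the same shape, 0 for
#'   background and 1..k for the k components. `count_components()`: the
#'   integer k.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[3:4, 3:4] <- 1
#' count_components(m)  # 2
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      h <- (p - 1L) %% H + 1L
      w <- (p - 1L) %/% H + 1L
      for (dh in -1:1) for (dw in -1:1) {
        hh <- h + dh; ww <- w + dw
        if (hh >= 1L && hh <= H && ww >= 1L && ww <= W) {
          q <- (ww - 1L) * H + hh
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' @rdname label_components
#' @export
count_components <- function(mask) {
  max(label_components(mask))
}

#' Count predicted components not touching any true cell
#'
#' Labels each image's predicted mask and counts components with no
#' overlap with the ground-truth cell mask. On synthetic data whose truth
#' masks exclude debris, these components are attributable to debris and
#' background noise — the artifacts the total-variation term suppresses.
#'
#' @param S predicted foreground batch (H x W x c x n).
#' @param tau binarization threshold.
#' @param masks H x W x n ground-truth cell masks.
#' @return Integer total over the batch.
#' @export
spurious_components <- function(S, tau, masks) {
  pred <- threshold_segment(S, tau)
  d <- dim(pred)
  masks <- array(masks, d)
  total <- 0L
  for (j in seq_len(d[3L])) {
    lab <- label_components(pred[, , j])
    k <- max(lab)
    if (k == 0L) next
    truth <- masks[, , j]
    for (comp in seq_len(k))
      if (!any(truth[lab == comp] != 0)) total <- total + 1L
  }
  total
}
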