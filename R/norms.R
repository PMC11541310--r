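#' Loss configuration for unsupervised separation
#'
#' Two nonnegative weights balance the loss: `lambda_sparse` scales the
#' l2,1 group-sparsity penalty on per-pixel foreground channel vectors and
#' `lambda_tv` scales the anisotropic total variation of each foreground
#' channel image. With `lambda_tv = 0` and one channel the loss reduces to
#' the RPCA objective, for which `default_lambda()` gives the standard
#' weight.
#'
#' @param lambda_sparse nonnegative sparsity weight.
#' @param lambda_tv nonnegative total-variation weight.
#' @param tv_full_boundary if `TRUE`, the TV term also penalizes horizontal
#'   differences in the last row and vertical differences in the last
#'   column; the default keeps the literal index range (both sums stop at
#'   H-1 and W-1).
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(lambda_sparse, lambda_tv = 0, tv_full_boundary = FALSE) {
  stopifnot(is.numeric(lambda_sparse), length(lambda_sparse) == 1L,
            is.numeric(lambda_tv), length(lambda_tv) == 1L)
  if (lambda_sparse < 0 || lambda_tv < 0)
    stop("loss weights must be nonnegative")
  structure(list(lambda_sparse = lambda_sparse, lambda_tv = lambda_tv,
                 tv_full_boundary = isTRUE(tv_full_boundary)),
            class = "loss_config")
}

check_finite_matrix <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M)) stop(what, " must be a numeric matrix")
  if (anyNA(M) || any(!is.finite(M))) stop(what, " has non-finite entries")
  M
}

#' Nuclear norm (sum of singular values)
#' @param M numeric matrix with finite entries.
#' @return Nonnegative scalar, invariant under transposition.
#' @export
nuclear_norm <- function(M) {
  check_finite_matrix(M)
  sum(svd(M, nu = 0L, nv = 0L)$d)
}

#' l2,1 norm: sum of columnwise Euclidean norms
#'
#' Applied to the c x mn unfolding of a foreground batch this sums the l2
#' norms of the per-pixel channel vectors; for a single row it coincides
#' with the l1 norm.
#' @param M numeric matrix with finite entries.
#' @return Nonnegative scalar.
#' @export
l21_norm <- function(M) {
  check_finite_matrix(M)
  sum(sqrt(.colSums(M^2, nrow(M), ncol(M))))
}

#' Anisotropic total variation of a single-channel image
#'
#' The double sum over h = 1..H-1 and w = 1..W-1 of
#' `|S[h+1,w] - S[h,w]| + |S[h,w+1] - S[h,w]|`. Note the literal index
#' range omits horizontal differences in the last row and vertical
#' differences in the last column; set `full_boundary = TRUE` for the
#' variant that includes them.
#'
#' @param img numeric H x W matrix, H >= 2, W >= 2.
#' @param full_boundary include the bottom-right boundary differences.
#' @return Nonnegative scalar; zero for constant images.
#' @examples
#' anisotropic_tv(matrix(c(0, 1, 1, 0), 2, 2))  # 2
#' @export
anisotropic_tv <- function(img, full_boundary = FALSE) {
  check_finite_matrix(img, "image")
  H <- nrow(img); W <- ncol(img)
  if (H < 2L || W < 2L) stop("TV needs H >= 2 and W >= 2")
  if (full_boundary) {
    sum(abs(img[-1L, , drop = FALSE] - img[-H, , drop = FALSE])) +
      sum(abs(img[, -1L, drop = FALSE] - img[, -W, drop = FALSE]))
  } else {
    cw <- seq_len(W - 1L); rh <- seq_len(H - 1L)
    sum(abs(img[-1L, cw, drop = FALSE] - img[rh, cw, drop = FALSE])) +
      sum(abs(img[rh, -1L, drop = FALSE] - img[rh, cw, drop = FALSE]))
  }
}

#' Batch separation loss
#'
#' The unsupervised training objective: nuclear norm of the cm x n unfolded
#' background, plus `lambda_sparse` times the l2,1 norm of the c x mn
#' unfolded foreground, plus `lambda_tv` times the summed anisotropic total
#' variation over all n*c foreground channel images. Sums are over the
#' batch, not means; the calibration of the weights assumes this.
#'
#' @param tensors a [separation_tensors()] object.
#' @param config a [loss_config()].
#' @return Nonnegative scalar loss.
#' @export
separation_loss <- function(tensors, config) {
  stopifnot(inherits(tensors, "separation_tensors"), inherits(config, "loss_config"))
  loss <- nuclear_norm(unfold_background(tensors$L)) +
    config$lambda_sparse * l21_norm(unfold_foreground_channels(tensors$S))
  if (config$lambda_tv > 0) {
    tv <- sum(vapply(foreground_as_channel_images(tensors$S), anisotropic_tv,
                     numeric(1L), full_boundary = config$tv_full_boundary))
    loss <- loss + config$lambda_tv * tv
  }
  loss
}

#' RPCA objective on unfolded matrices
#'
#' Nuclear norm of the low-rank matrix plus `lambda_sparse` times the
#' entrywise l1 norm of the sparse matrix. For single-channel batches with
#' zero TV weight this equals [separation_loss()] on the corresponding
#' tensors.
#'
#' @param L_mat,S_mat numeric matrices with finite entries.
#' @param lambda_sparse nonnegative weight.
#' @return Nonnegative scalar.
#' @export
rpca_objective <- function(L_mat, S_mat, lambda_sparse) {
  stopifnot(lambda_sparse >= 0)
  check_finite_matrix(S_mat)
  nuclear_norm(L_mat) + lambda_sparse * sum(abs(S_mat))
}

#' Standard sparsity weight for the RPCA special case
#'
#' `1 / sqrt(max(m, n))` for m pixels (times channels) and batch size n —
#' the theoretically motivated choice when the TV weight is zero. With TV
#' in play a smaller value is recommended since TV also penalizes the
#' foreground.
#'
#' @param m pixel count per image (positive integer).
#' @param n batch size (positive integer).
#' @return Positive scalar `1/sqrt(max(m, n))`.
#' @examples
#' default_lambda(81920, 32)   # ~3.49e-3
#' default_lambda(262144, 135) # 1/512
#' @export
default_lambda <- function(m, n) {
  stopifnot(length(m) == 1L, length(n) == 1L)
  if (!is.finite(m) || !is.finite(n) || m < 1 || n < 1)
    stop("m and n must be positive")
  1 / sqrt(max(m, n))
}
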