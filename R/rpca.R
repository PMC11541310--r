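#' Elementwise soft-thresholding (proximal operator of the l1 norm)
#' @param M numeric matrix or array.
#' @param tau nonnegative threshold.
#' @return `sign(M) * pmax(|M| - tau, 0)`, same shape as `M`.
#' @export
soft_threshold <- function(M, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("tau must be a nonnegative scalar")
  sign(M) * pmax(abs(M) - tau, 0)
}

#' Singular value thresholding (proximal operator of the nuclear norm)
#' @param M numeric matrix with finite entries.
#' @param tau nonnegative threshold applied to the singular values.
#' @return Matrix of the same shape with soft-thresholded singular values.
#' @export
singular_value_threshold <- function(M, tau) {
  check_finite_matrix(M)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("tau must be a nonnegative scalar")
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' ADMM solver configuration for RPCA
#'
#' Defaults follow the standard inexact augmented-Lagrangian recipe:
#' penalty initialized at `1.25 / ||D||_2` with growth factor `rho = 1.5`,
#' stopping at a relative Frobenius feasibility residual of `1e-7` or 1000
#' iterations, in double precision.
#'
#' @param lambda_sparse sparsity weight; `NULL` means `default_lambda()`
#'   of the matrix passed to [rpca_admm()].
#' @param mu0 initial penalty; `NULL` means `1.25 / ||D||_2`.
#' @param rho penalty growth factor, >= 1.
#' @param tol relative residual tolerance, > 0.
#' @param max_iter maximum iterations, >= 1.
#' @return A list of class `"rpca_config"`.
#' @export
rpca_config <- function(lambda_sparse = NULL, mu0 = NULL, rho = 1.5,
                        tol = 1e-7, max_iter = 1000L) {
  if (tol <= 0) stop("tol must be positive")
  if (rho < 1) stop("rho must be >= 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(lambda_sparse = lambda_sparse, mu0 = mu0, rho = rho,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "rpca_config")
}

#' Robust PCA by the alternating direction method of multipliers
#'
#' Decomposes `D = L + S` by minimizing `||L||_* + lambda * ||S||_1`,
#' alternating singular value thresholding for `L`, soft thresholding for
#' `S`, and dual ascent on the multiplier of the equality constraint, with
#' the penalty grown by `rho` each iteration. This is the training-free
#' baseline the batch separation loss generalizes.
#'
#' @param D_mat numeric matrix, at least 2 x 2, finite entries.
#' @param config an [rpca_config()].
#' @return An object of class `"rpca_result"`: list with `low_rank`,
#'   `sparse`, `iterations`, `residual` (relative Frobenius feasibility
#'   residual), `converged`, `lambda_sparse`, `objective`.
#' @examples
#' D <- tcrossprod(rnorm(30), rnorm(20))
#' fit <- rpca_admm(D, rpca_config(lambda_sparse = 10))
#' fit$iterations
#' @export
rpca_admm <- function(D_mat, config = rpca_config()) {
  check_finite_matrix(D_mat, "D")
  if (nrow(D_mat) < 2L || ncol(D_mat) < 2L) stop("D must be at least 2 x 2")
  stopifnot(inherits(config, "rpca_config"))
  lam <- config$lambda_sparse
  if (is.null(lam)) lam <- default_lambda(nrow(D_mat), ncol(D_mat))
  d_norm <- sqrt(sum(D_mat^2))
  if (d_norm == 0) {
    Z <- matrix(0, nrow(D_mat), ncol(D_mat))
    return(structure(list(low_rank = Z, sparse = Z, iterations = 0L,
                          residual = 0, converged = TRUE, lambda_sparse = lam,
                          objective = 0),
                     class = "rpca_result"))
  }
  spec <- svd(D_mat, nu = 0L, nv = 0L)$d[1L]
  mu <- if (is.null(config$mu0)) 1.25 / spec else config$mu0
  mu_max <- mu * 1e7
  # dual warm start scaled so the first updates are well-conditioned
  Y <- D_mat / max(spec, max(abs(D_mat)) / lam)
  L <- matrix(0, nrow(D_mat), ncol(D_mat))
  S <- L
  it <- 0L
  res <- Inf
  while (it < config$max_iter) {
    it <- it + 1L
    L <- singular_value_threshold(D_mat - S + Y / mu, 1 / mu)
    S <- soft_threshold(D_mat - L + Y / mu, lam / mu)
    R <- D_mat - L - S
    Y <- Y + mu * R
    mu <- min(mu * config$rho, mu_max)
    res <- sqrt(sum(R^2)) / d_norm
    if (res <= config$tol) break
  }
  structure(list(low_rank = L, sparse = S, iterations = it, residual = res,
                 converged = res <= config$tol, lambda_sparse = lam,
                 objective = rpca_objective(L, S, lam)),
            class = "rpca_result")
}

#' @export
print.rpca_result <- function(x, ...) {
  cat(sprintf("rpca_result: %d x %d, %d iterations, residual %.2e%s\n",
              nrow(x$low_rank), ncol(x$low_rank), x$iterations, x$residual,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname tidy_cytosep
#' @method glance rpca_result
#' @export
glance.rpca_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, residual = x$residual,
                 converged = x$converged, lambda_sparse = x$lambda_sparse,
                 objective = x$objective,
                 rank = sum(svd(x$low_rank, nu = 0L, nv = 0L)$d >
                              max(dim(x$low_rank)) * .Machine$double.eps *
                              max(svd(x$low_rank, nu = 0L, nv = 0L)$d, 1)),
                 sparsity = mean(x$sparse != 0))
}

#' RPCA background removal on an image stack
#'
#' Vectorizes a single-channel image batch into an n x m matrix (one row
#' per image, row-major pixel order), runs [rpca_admm()], and folds the
#' sparse component back into per-image foregrounds. The absolute value of
#' the sparse component is the per-pixel foreground intensity used for
#' thresholding.
#'
#' @param images single-channel image batch (H x W x 1 x n array, or
#'   anything [as_image_batch()] accepts).
#' @param config an [rpca_config()].
#' @return A list: `foreground` (signed sparse component, H x W x 1 x n),
#'   `background` (low-rank component), `intensity` (absolute foreground),
#'   and `fit` (the underlying `rpca_result`).
#' @export
rpca_image_stack <- function(images, config = rpca_config()) {
  images <- check_batch(images)
  d <- batch_dims(images)
  if (d$c != 1L) stop("RPCA image stack expects single-channel images")
  D_mat <- t(unfold_background(images))          # n x m, rows are images
  fit <- rpca_admm(D_mat, config)
  S <- fold_background(t(fit$sparse), d$H, d$W, 1L)
  L <- fold_background(t(fit$low_rank), d$H, d$W, 1L)
  list(foreground = S, background = L, intensity = abs(S), fit = fit)
}
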