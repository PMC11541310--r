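#' Image batch arrays and separation tensors
#'
#' `cytosep` stores a batch of n images with c channels of size H x W as a
#' plain 4-D array with `dim = c(H, W, c, n)`. Pixel values of input images
#' live in \[0, 1\]; predicted foregrounds are signed (cells darker than the
#' background have negative values). `as_image_batch()` promotes a matrix
#' (one grayscale image) or a 3-D array (one multi-channel image) to the
#' canonical 4-D layout.
#'
#' @param x matrix (H x W), 3-D array (H x W x c) or 4-D array (H x W x c x n).
#' @return A 4-D numeric array of dimension `c(H, W, c, n)`.
#' @examples
#' dim(as_image_batch(matrix(0, 4, 5)))  # 4 5 1 1
#' @export
as_image_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  else if (is.array(x) && length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 4L || !is.numeric(x))
    stop("expected a numeric matrix, 3-D array or 4-D array (H x W x c x n)")
  x
}

batch_dims <- function(x) {
  d <- dim(x)
  list(H = d[1L], W = d[2L], c = d[3L], n = d[4L], m = d[1L] * d[2L])
}

check_batch <- function(x, what = "image batch") {
  x <- as_image_batch(x)
  d <- batch_dims(x)
  if (d$n < 1L) stop(what, ": need at least one image")
  if (!d$c %in% c(1L, 3L)) stop(what, ": channel count must be 1 or 3, got ", d$c)
  if (d$H < 2L || d$W < 2L) stop(what, ": images must be at least 2 x 2")
  if (anyNA(x) || any(!is.finite(x))) stop(what, ": non-finite pixel values")
  x
}

#' Bundle an input batch with its foreground/background split
#'
#' The background is defined as `L = D - S`, so the additivity identity
#' `L + S = D` holds exactly (bit-for-bit) by construction. Either `S` or
#' `L` may be supplied; the other is derived.
#'
#' @param D input image batch in \[0, 1\] (anything `as_image_batch()` accepts).
#' @param S signed foreground batch, same shape as `D`.
#' @param L background batch, same shape as `D`; used when `S` is missing.
#' @return An object of class `"separation_tensors"`: a list with elements
#'   `D`, `S`, `L` (4-D arrays of identical shape).
#' @examples
#' D <- array(runif(2 * 1 * 4 * 4), c(4, 4, 1, 2))
#' st <- separation_tensors(D, S = array(0, dim(D)))
#' stopifnot(identical(st$L, D))
#' @export
separation_tensors <- function(D, S = NULL, L = NULL) {
  D <- check_batch(D, "D")
  if (is.null(S) && is.null(L)) stop("supply S or L")
  if (is.null(S)) {
    L <- check_batch(L, "L")
    if (!identical(dim(L), dim(D))) stop("L and D shapes differ")
    S <- D - L
  } else {
    S <- check_batch(S, "S")
    if (!identical(dim(S), dim(D))) stop("S and D shapes differ")
    L <- D - S
  }
  structure(list(D = D, S = S, L = L), class = "separation_tensors")
}

#' @export
print.separation_tensors <- function(x, ...) {
  d <- batch_dims(x$D)
  cat(sprintf("separation_tensors: n=%d images, c=%d, %d x %d (m=%d)\n",
              d$n, d$c, d$H, d$W, d$m))
  invisible(x)
}

#' Unfold a batch into a cm x n matrix (one column per image)
#'
#' Column j is the vectorization of image j: channel-major, and row-major
#' within each channel (pixel (h, w) sits at flat index (h-1)*W + (w-1),
#' 0-based). This is the unfolding whose nuclear norm measures background
#' redundancy across the batch.
#'
#' @param x 4-D array (H x W x c x n).
#' @return A `(c*H*W) x n` numeric matrix.
#' @seealso [fold_background()] for the inverse.
#' @export
unfold_background <- function(x) {
  x <- check_batch(x)
  d <- batch_dims(x)
  m <- aperm(x, c(2L, 1L, 3L, 4L))     # W fastest, then H, then channel
  dim(m) <- c(d$W * d$H * d$c, d$n)
  m
}

#' Invert [unfold_background()]
#' @param M `(c*H*W) x n` matrix.
#' @param H,W,channels target image geometry.
#' @return 4-D array (H x W x channels x n).
#' @export
fold_background <- function(M, H, W, channels = 1L) {
  if (!is.matrix(M) || nrow(M) != H * W * channels)
    stop("matrix has ", nrow(M), " rows; expected c*H*W = ", H * W * channels)
  a <- array(M, c(W, H, channels, ncol(M)))
  aperm(a, c(2L, 1L, 3L, 4L))
}

#' Unfold a batch into a c x mn matrix of per-pixel channel vectors
#'
#' Each column is the c-vector of channel values at one pixel of one image.
#' Columns are ordered image-major (all m pixels of image 1, then image 2,
#' ...), row-major within an image. The l2,1 norm of this matrix is the
#' group-sparsity penalty on the foreground.
#'
#' @param x 4-D array (H x W x c x n).
#' @return A `c x (H*W*n)` numeric matrix.
#' @export
unfold_foreground_channels <- function(x) {
  x <- check_batch(x)
  d <- batch_dims(x)
  m <- aperm(x, c(3L, 2L, 1L, 4L))     # channel, then W fastest, H, image
  dim(m) <- c(d$c, d$W * d$H * d$n)
  m
}

#' Invert [unfold_foreground_channels()]
#' @param M `c x (H*W*n)` matrix.
#' @param H,W target image geometry.
#' @return 4-D array (H x W x c x n).
#' @export
fold_foreground_channels <- function(M, H, W) {
  if (!is.matrix(M) || ncol(M) %% (H * W) != 0L)
    stop("column count is not a multiple of H*W")
  a <- array(M, c(nrow(M), W, H, ncol(M) / (H * W)))
  aperm(a, c(3L, 2L, 1L, 4L))
}

#' Split a foreground batch into its n*c single-channel images
#'
#' Yields one H x W matrix per (image, channel) pair — image-major, channel
#' minor — using the same row-major pixel order as the other unfoldings, so
#' reassembling the list reproduces the batch exactly. The anisotropic total
#' variation term of the separation loss sums over these images.
#'
#' @param x 4-D array (H x W x c x n).
#' @return A list of `n*c` numeric H x W matrices.
#' @export
foreground_as_channel_images <- function(x) {
  x <- check_batch(x)
  d <- batch_dims(x)
  out <- vector("list", d$n * d$c)
  i <- 0L
  for (j in seq_len(d$n)) for (k in seq_len(d$c)) {
    i <- i + 1L
    out[[i]] <- x[, , k, j]
  }
  out
}
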