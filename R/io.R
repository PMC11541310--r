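#' Read PNG/TIFF images into a normalized batch
#'
#' Pixel values are normalized to \[0, 1\] by dividing by the dtype
#' maximum (the PNG/TIFF readers do this for 8- and 16-bit integer data;
#' floating-point TIFF is passed through). Grayscale images yield c = 1,
#' RGB yields c = 3, and an alpha channel is dropped. All images must
#' share dimensions, or a target size must be given for resizing
#' (area averaging for integer downscale factors, bilinear otherwise).
#'
#' @param paths character vector of PNG or TIFF file paths, or a directory
#'   (read in sorted order).
#' @param resize optional `c(H, W)` target size.
#' @return A 4-D image batch (H x W x c x n) with `names(dim)` unset and
#'   attribute `"files"` carrying the source paths.
#' @export
read_images <- function(paths, resize = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0L) stop("no image files to read")
  imgs <- lapply(paths, read_one_image)
  if (!is.null(resize))
    imgs <- lapply(imgs, resize_image, H = resize[1L], W = resize[2L])
  dims <- vapply(imgs, dim, integer(3L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]) ||
      any(dims[3L, ] != dims[3L, 1L]))
    stop("images have mixed dimensions; supply `resize` or fix the inputs")
  out <- array(0, c(dims[, 1L], length(imgs)))
  for (j in seq_along(imgs)) out[, , , j] <- imgs[[j]]
  attr(out, "files") <- paths
  out
}

# read a single file as an H x W x c array in [0, 1]
read_one_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  lower <- tolower(path)
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else stop("unsupported image format (need PNG or TIFF): ", path)
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 2L) img <- img[, , 1L, drop = FALSE]          # gray+alpha
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]         # drop alpha
  img
}

# area-average for integer downscale factors, bilinear otherwise
resize_image <- function(img, H, W) {
  d <- dim(img)
  if (d[1L] == H && d[2L] == W) return(img)
  out <- array(0, c(H, W, d[3L]))
  if (d[1L] %% H == 0L && d[2L] %% W == 0L) {
    fh <- d[1L] %/% H; fw <- d[2L] %/% W
    for (k in seq_len(d[3L])) {
      m <- img[, , k]
      m <- matrix(.colMeans(matrix(m, fh, H * d[2L]), fh, H * d[2L]), H, d[2L])
      m <- t(matrix(.colMeans(matrix(t(m), fw, W * H), fw, W * H), W, H))
      out[, , k] <- m
    }
  } else {
    ih <- pmin(pmax((seq_len(H) - 0.5) * d[1L] / H + 0.5, 1), d[1L])
    iw <- pmin(pmax((seq_len(W) - 0.5) * d[2L] / W + 0.5, 1), d[2L])
    h0 <- pmin(floor(ih), d[1L] - 1L); w0 <- pmin(floor(iw), d[2L] - 1L)
    ah <- ih - h0; aw <- iw - w0
    for (k in seq_len(d[3L])) {
      m <- img[, , k]
      top <- m[h0, w0, drop = FALSE] * (1 - aw)[col(matrix(0, H, W))] +
        m[h0, w0 + 1L, drop = FALSE] * aw[col(matrix(0, H, W))]
      bot <- m[h0 + 1L, w0, drop = FALSE] * (1 - aw)[col(matrix(0, H, W))] +
        m[h0 + 1L, w0 + 1L, drop = FALSE] * aw[col(matrix(0, H, W))]
      out[, , k] <- top * (1 - ah) + bot * ah
    }
  }
  out
}

#' Write separation results to disk
#'
#' Writes, per image: a foreground visualization (`S + 0.8` clipped to
#' \[0, 1\], PNG — the uniform 0.8 stands in for an imaginary clean
#' background), the raw signed foreground (floating-point TIFF, since `S`
#' is negative on cells), the background `L` (PNG, clipped), and the
#' binary mask (PNG, 0/255) when a threshold is given. Also writes a
#' metrics table (CSV: image, threshold, Dice when truth masks are
#' supplied), the training history (CSV) when available, and the resolved
#' run configuration (YAML).
#'
#' @param tensors a [separation_tensors()] object.
#' @param outdir output directory (created if missing).
#' @param tau optional binarization threshold; masks and Dice need it.
#' @param truth_masks optional H x W x n ground-truth masks for Dice.
#' @param history optional history tibble (e.g. from a `cytosep_fit`).
#' @param run_config optional list serialized to `config.yaml`.
#' @return Invisibly, a character vector of the files written.
#' @export
write_outputs <- function(tensors, outdir, tau = NULL, truth_masks = NULL,
                          history = NULL, run_config = NULL) {
  stopifnot(inherits(tensors, "separation_tensors"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", outdir)
  unlink(probe)

  d <- batch_dims(tensors$D)
  files <- character(0)
  masks <- if (!is.null(tau)) threshold_segment(tensors$S, tau) else NULL
  for (j in seq_len(d$n)) {
    id <- sprintf("%04d", j)
    vis <- clip01(drop3(tensors$S[, , , j, drop = FALSE]) + 0.8)
    f <- file.path(outdir, paste0("foreground_vis_", id, ".png"))
    png::writePNG(vis, f); files <- c(files, f)
    f <- file.path(outdir, paste0("foreground_raw_", id, ".tif"))
    write_raw_foreground(tensors$S[, , , j, drop = FALSE], f)
    files <- c(files, f)
    f <- file.path(outdir, paste0("background_", id, ".png"))
    png::writePNG(clip01(drop3(tensors$L[, , , j, drop = FALSE])), f)
    files <- c(files, f)
    if (!is.null(masks)) {
      f <- file.path(outdir, paste0("mask_", id, ".png"))
      png::writePNG(masks[, , j], f); files <- c(files, f)
    }
  }

  metrics <- tibble::tibble(image = seq_len(d$n),
                            threshold = if (is.null(tau)) NA_real_ else tau,
                            dice = NA_real_)
  if (!is.null(masks) && !is.null(truth_masks)) {
    truth_masks <- array(truth_masks, c(d$H, d$W, d$n))
    metrics$dice <- vapply(seq_len(d$n), function(j)
      dice(masks[, , j], truth_masks[, , j]), numeric(1L))
  }
  f <- file.path(outdir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE); files <- c(files, f)
  if (!is.null(history)) {
    f <- file.path(outdir, "history.csv")
    utils::write.csv(as.data.frame(history), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(run_config)) {
    f <- file.path(outdir, "config.yaml")
    yaml::write_yaml(run_config, f); files <- c(files, f)
  }
  invisible(files)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# drop the image axis (and a singleton channel axis) for the PNG writers
drop3 <- function(x) {
  d <- dim(x)
  if (d[3L] == 1L) matrix(x, d[1L], d[2L]) else array(x, d[1:3])
}

#' Persist signed foregrounds as floating-point TIFF
#'
#' TIFF raster values live in \[0, 1\], so the signed foreground is stored
#' in the affine encoding `(S + 1) / 2` as 32-bit float samples (values
#' outside \[-1, 1\] are clamped; foregrounds of unit-range images satisfy
#' this). `read_raw_foreground()` inverts the encoding.
#'
#' @param S a single foreground image (H x W x c array, or H x W x c x 1).
#' @param path TIFF file path.
#' @return `read_raw_foreground()` returns the signed H x W x c array.
#' @export
write_raw_foreground <- function(S, path) {
  if (length(dim(S)) == 4L) S <- array(S, dim(S)[1:3])
  enc <- (pmin(pmax(S, -1), 1) + 1) / 2
  tiff::writeTIFF(drop3(array(enc, c(dim(S), 1L))), path,
                  bits.per.sample = 32L, reduce = TRUE)
  invisible(path)
}

#' @rdname write_raw_foreground
#' @export
read_raw_foreground <- function(path) {
  x <- tiff::readTIFF(path)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  2 * x - 1
}

#' Serialize and restore run configurations
#'
#' A run is fully reproducible from its serialized configuration plus
#' seed: `write_run_config()` writes YAML, `read_run_config()` parses it
#' back, and the two are mutual inverses (serialize-parse-serialize is a
#' fixed point).
#'
#' @param config a named list (typically network, training, loss, RPCA and
#'   synthetic settings plus paths and seed).
#' @param path YAML file path.
#' @return `read_run_config()` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Save and load a trained model
#'
#' The checkpoint embeds the full network configuration, so
#' [load_model()] can validate compatibility before prediction.
#'
#' @param model a `separation_model` or `cytosep_fit`.
#' @param path file path (RDS).
#' @return `load_model()` returns the `separation_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "cytosep_fit")) model <- model$model
  stopifnot(inherits(model, "separation_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "separation_model") || is.null(model$config))
    stop("not a cytosep model checkpoint: ", path)
  model
}
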