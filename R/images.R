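#' Image and mask containers
#'
#' Light S3 wrappers around base matrices/arrays. An `rgb_image` is an
#' `H x W x 3` array of intensities in `[0, 1]`; a `gray_image` is an `H x W`
#' matrix in `[0, 1]`. Both carry the physical pixel scale in micrometres per
#' pixel (`px_scale_um`), defaulting to 0.899 um/px, the scale of a typical
#' 10x biopsy region of interest.
#'
#' @param pixels numeric array (`H x W x 3`) or matrix (`H x W`) in `[0, 1]`.
#' @param px_scale_um physical pixel size, micrometres per pixel (> 0).
#' @return An object of class `rgb_image` or `gray_image`.
#' @examples
#' img <- rgb_image(array(0.5, c(32, 32, 3)))
#' g   <- gray_image(matrix(0.2, 32, 32))
#' @export
rgb_image <- function(pixels, px_scale_um = 0.899) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_image requires an H x W x 3 array")
  check_px_scale(px_scale_um)
  check_intensities(pixels)
  if (any(dim(pixels)[1:2] < 16L))
    stop("image too small: H and W must both be >= 16")
  structure(pixels, px_scale_um = px_scale_um,
            class = c("rgb_image", class(array(0))))
}

#' @rdname rgb_image
#' @export
gray_image <- function(pixels, px_scale_um = 0.899) {
  if (!is.matrix(pixels)) stop("gray_image requires an H x W matrix")
  check_px_scale(px_scale_um)
  check_intensities(pixels)
  structure(pixels, px_scale_um = px_scale_um,
            class = c("gray_image", "matrix", "array"))
}

#' Binary masks and labelled fibre masks
#'
#' A `binary_mask` is a logical matrix with a `semantics` flag saying whether
#' TRUE marks connective-tissue boundary (`"boundary"`) or fibre interior
#' (`"fibre"`). A `label_mask` is an integer matrix in which 0 is
#' background/boundary and labels `1..K` are individual fibres; label ids are
#' consecutive and each labels one 8-connected region.
#'
#' @param pixels logical matrix (mask) or non-negative integer matrix (labels).
#' @param semantics `"boundary"` or `"fibre"`.
#' @param px_scale_um micrometres per pixel.
#' @return A `binary_mask` or `label_mask` object.
#' @export
binary_mask <- function(pixels, semantics = c("boundary", "fibre")) {
  semantics <- match.arg(semantics)
  if (!is.matrix(pixels)) stop("binary_mask requires a matrix")
  storage.mode(pixels) <- "logical"
  structure(pixels, semantics = semantics,
            class = c("binary_mask", "matrix", "array"))
}

#' @rdname binary_mask
#' @export
label_mask <- function(pixels, px_scale_um = 0.899) {
  if (!is.matrix(pixels)) stop("label_mask requires a matrix")
  check_px_scale(px_scale_um)
  if (any(pixels < 0)) stop("labels must be non-negative")
  storage.mode(pixels) <- "integer"
  structure(pixels, px_scale_um = px_scale_um,
            class = c("label_mask", "matrix", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, %.3f um/px\n", d[1], d[2], px_scale(x)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gray_image> %d x %d px, %.3f um/px, range [%.3f, %.3f]\n",
              d[1], d[2], px_scale(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d fibres, %.3f um/px\n",
              nrow(x), ncol(x), n_labels(x), px_scale(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s> %d x %d px, %d TRUE\n",
              attr(x, "semantics"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

px_scale <- function(x, default = 0.899) {
  s <- attr(x, "px_scale_um")
  if (is.null(s)) default else s
}

n_labels <- function(labels) {
  m <- max(labels)
  if (is.finite(m)) as.integer(m) else 0L
}

check_px_scale <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("px_scale_um must be a single positive number")
  invisible(s)
}

check_intensities <- function(x, tol = 1e-9) {
  if (anyNA(x) || any(!is.finite(x))) stop("image contains non-finite values")
  if (min(x) < -tol || max(x) > 1 + tol)
    stop("image intensities must lie within [0, 1]")
  invisible(x)
}

# strip classes/attrs for raw numeric work
as_plain <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Read an RGB histology image from TIFF or PNG
#'
#' 8/16-bit integer images are rescaled to `[0, 1]`; an alpha channel, if
#' present, is dropped; grayscale files are replicated across three channels.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param px_scale_um micrometres per pixel to attach.
#' @return An [rgb_image].
#' @export
read_image <- function(path, px_scale_um = 0.899) {
  if (!file.exists(path)) stop("input image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(pmin(pmax(px, 0), 1), px_scale_um = px_scale_um)
}

#' Write / read a label mask as a 16-bit image
#'
#' TIFF masks are written as true 16-bit gray (one label id per gray level).
#' PNG masks are written as a two-channel image holding the high and low
#' bytes of the 16-bit label id (the `png` writer is 8-bit only); both forms
#' are read back exactly.
#'
#' @param labels a [label_mask] (at most 65535 labels).
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   returns a [label_mask].
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels cannot be stored in 16 bits")
  lab <- as_plain(labels)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      hi <- (lab %/% 256L) / 255
      lo <- (lab %% 256L) / 255
      png::writePNG(array(c(hi, lo, 0 * lo), c(dim(lab), 3L)), target = path)
    },
    tif = , tiff = tiff::writeTIFF(lab / 65535, where = path,
                                   bits.per.sample = 16L),
    stop("unsupported label format: .", ext)
  )
  invisible(path)
}

#' @rdname write_label_mask
#' @param px_scale_um micrometres per pixel to attach on read.
#' @export
read_label_mask <- function(path, px_scale_um = 0.899) {
  if (!file.exists(path)) stop("label mask not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported label format: .", ext)
  )
  if (length(dim(m)) == 3L && dim(m)[3] >= 2L) {
    lab <- round(m[, , 1] * 255) * 256L + round(m[, , 2] * 255)
  } else {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    lab <- round(m * 65535)
  }
  label_mask(matrix(as.integer(lab), nrow(lab), ncol(lab)),
             px_scale_um = px_scale_um)
}

#' Write a gray image as 32-bit float TIFF (e.g. the diffusion output)
#' @param gray a [gray_image].
#' @param path output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(gray, path) {
  tiff::writeTIFF(as_plain(gray), where = path, bits.per.sample = 32L)
  invisible(path)
}

#' Write an RGB image as TIFF or PNG
#' @param img an [rgb_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  px <- pmin(pmax(as_plain_rgb(img), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, target = path),
    tif = , tiff = tiff::writeTIFF(px, where = path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

as_plain_rgb <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
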