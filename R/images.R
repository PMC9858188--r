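# Raster containers and helpers. Images are H x W x 3 integer arrays with
# 8-bit channel values; masks are logical H x W matrices. Both carry `level`
# and `downsample` attributes when they belong to a slide pyramid.

#' Construct an 8-bit RGB image
#'
#' @param pixels H x W x 3 array of channel values in \[0, 255\].
#' @param level pyramid level index (0 = full resolution).
#' @returns An object of class `rgb_image`: a list with `pixels` (integer
#'   array), `level` and `downsample` (`2^level`).
#' @export
rgb_image <- function(pixels, level = 0L) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  level <- as.integer(level)
  structure(
    list(pixels = pixels, level = level, downsample = 2L^level),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d, level %d (downsample %d)\n",
              d[1], d[2], x$level, x$downsample))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

# Accept either an rgb_image or a bare array.
img_pixels <- function(img) {
  if (inherits(img, "rgb_image")) img$pixels else img
}

img_level <- function(img) {
  if (inherits(img, "rgb_image")) img$level else 0L
}

#' Tag a logical matrix as a pyramid-level mask
#'
#' @param m logical matrix.
#' @param level pyramid level the mask was computed at.
#' @returns The matrix with `level` and `downsample` attributes set.
#' @export
binary_mask <- function(m, level = 0L) {
  stopifnot(is.matrix(m))
  storage.mode(m) <- "logical"
  attr(m, "level") <- as.integer(level)
  attr(m, "downsample") <- 2L^as.integer(level)
  m
}

mask_downsample <- function(mask) {
  ds <- attr(mask, "downsample")
  if (is.null(ds)) 1L else as.integer(ds)
}

# Rec. 601 luma in [0, 255].
luma <- function(img) {
  p <- img_pixels(img)
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

# HSV channels: h in [0, 360), s and v in [0, 1].
rgb_to_hsv_channels <- function(img) {
  p <- img_pixels(img)
  d <- dim(p)
  m <- rbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

# Round half away from zero; scanner-style 8-bit quantization.
round_half_up <- function(x) floor(x + 0.5)

# 2x box-filter downsample of a matrix; odd dimensions replicate the edge.
down2_mat <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  if (h %% 2L) m <- rbind(m, m[h, , drop = FALSE])
  if (w %% 2L) m <- cbind(m, m[, w, drop = FALSE])
  i <- seq(1L, nrow(m), 2L)
  j <- seq(1L, ncol(m), 2L)
  (m[i, j] + m[i + 1L, j] + m[i, j + 1L] + m[i + 1L, j + 1L]) / 4
}

#' Build a 2x-downsampled image pyramid
#'
#' Level `k` has dimensions `ceiling(dim0 / 2^k)`; pixel values are 2x2 box
#' means, re-quantized half-up to 8 bits.
#'
#' @param pixels level-0 H x W x 3 array (0--255).
#' @param n_levels number of levels including level 0.
#' @returns List of [rgb_image] objects, one per level.
#' @export
build_pyramid <- function(pixels, n_levels = 3L) {
  pixels <- img_pixels(pixels)
  out <- vector("list", n_levels)
  out[[1]] <- rgb_image(pixels, level = 0L)
  cur <- pixels
  for (k in seq_len(n_levels - 1L)) {
    nxt <- vapply(
      1:3,
      function(ch) down2_mat(cur[, , ch]),
      matrix(0, ceiling(nrow(cur) / 2), ceiling(ncol(cur) / 2))
    )
    cur <- round_half_up(nxt)
    out[[k + 1L]] <- rgb_image(cur, level = k)
  }
  out
}

#' Extract a level-0 tile from an image
#'
#' @param img level-0 image ([rgb_image] or array).
#' @param row0,col0 0-based top-left corner.
#' @param size tile side in pixels; the tile is `[row0, row0+size) x
#'   [col0, col0+size)`.
#' @returns H x W x 3 integer array.
#' @export
extract_tile <- function(img, row0, col0, size) {
  p <- img_pixels(img)
  d <- dim(p)
  r <- (row0 + 1L):min(row0 + size, d[1])
  cc <- (col0 + 1L):min(col0 + size, d[2])
  p[r, cc, , drop = FALSE]
}

#' Write an RGB patch as PNG
#' @param img image to write.
#' @param path output file.
#' @export
write_patch_png <- function(img, path) {
  png::writePNG(img_pixels(img) / 255, target = path)
  invisible(path)
}

#' Read an RGB patch from PNG
#' @param path PNG file.
#' @returns [rgb_image] at level 0.
#' @export
read_patch_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  rgb_image(round_half_up(a[, , 1:3, drop = FALSE] * 255))
}

#' Write a slide pyramid as multi-page TIFF (one page per level)
#' @param levels list of [rgb_image] objects (level 0 first).
#' @param path output file.
#' @export
write_slide_tiff <- function(levels, path) {
  pages <- lapply(levels, function(l) img_pixels(l) / 255)
  tiff::writeTIFF(pages, where = path)
  invisible(path)
}

#' Read a slide pyramid from multi-page TIFF
#' @param path TIFF file written by [write_slide_tiff()] (or any multi-page
#'   TIFF whose pages halve in size).
#' @returns List of [rgb_image] objects.
#' @export
read_slide_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(seq_along(pages), function(k) {
    a <- pages[[k]]
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    rgb_image(round_half_up(a[, , 1:3, drop = FALSE] * 255), level = k - 1L)
  })
}

#' Write an integer label image as 16-bit TIFF
#' @param labels integer matrix (0 = background; at most 65535 labels).
#' @param path output file.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, where = path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_label_tiff()]
#' @param path TIFF file.
#' @returns Integer matrix.
#' @export
read_label_tiff <- function(path) {
  a <- tiff::readTIFF(path)
  matrix(as.integer(round(a * 65535)), nrow(a), ncol(a))
}

# EBImage interop: matrices pass straight through (both are row x col here;
# morphological and distance operations are transpose-symmetric).
as_ebi <- function(m) EBImage::Image(m * 1)
from_ebi <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}
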