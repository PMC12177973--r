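#' Read a raster image
#'
#' Reads a PNG, TIFF or JPEG file into an [rgb_image()]. Grayscale inputs
#' are replicated to three identical channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path) || isTRUE(file.info(path)$size == 0))
    stop("cannot read image '", path, "': file missing or empty",
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch(switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    tif = , tiff = read_tiff(path),
    stop("unsupported image format '", ext, "'", call. = FALSE)),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ext %in% c("tif", "tiff")) return(rgb_image(x))
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] == 2L)  # gray + alpha
    x <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  rgb_image(round(x * 255))
}

#' Write a raster image
#'
#' @param img An [rgb_image()] or [rgba_image()].
#' @param path Output path; the extension selects PNG, JPEG or TIFF
#'   (TIFF only for RGB).
#' @param quality JPEG quality in (0, 1].
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 0.95) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(img) / 255
  switch(ext,
    png = png::writePNG(x, path),
    jpg = , jpeg = jpeg::writeJPEG(x[, , 1:3, drop = FALSE], path,
                                   quality = quality),
    tif = , tiff = write_tiff_rgb8(unclass(img)[, , 1:3, drop = FALSE], path),
    stop("unsupported image format '", ext, "'", call. = FALSE))
  invisible(path)
}

#' Write and read segmentation masks
#'
#' Binary masks are stored as 0/255 8-bit PNG, labeled masks as 16-bit
#' grayscale PNG, and probability masks as 32-bit float TIFF. All three
#' round-trip through [read_mask()] (probability masks exactly for values
#' representable in 32-bit floats).
#'
#' @param mask A [binary_mask()], [labeled_mask()] or [probability_mask()].
#' @param path Output path (`.png` for binary/labeled, `.tif`/`.tiff` for
#'   probability masks).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write mask: directory '", dirname(path), "' does not exist",
         call. = FALSE)
  if (inherits(mask, "binary_mask")) {
    png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  } else if (inherits(mask, "labeled_mask")) {
    if (max(mask) > 65535L)
      stop("labeled masks with more than 65535 components cannot be stored",
           call. = FALSE)
    cpp_write_png16(as_plain(mask), path.expand(path))
  } else if (inherits(mask, "probability_mask")) {
    write_tiff_float(as_plain(mask), path)
  } else stop("unsupported mask type", call. = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @param kind Mask kind to read: `"auto"` infers binary for 8-bit PNG,
#'   labeled for 16-bit PNG, probability for float TIFF.
#' @export
read_mask <- function(path, kind = c("auto", "binary", "labeled",
                                     "probability")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("cannot read mask '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- read_tiff(path)
    if (!is.matrix(v)) stop("'", path, "' is not a probability mask",
                            call. = FALSE)
    return(probability_mask(pmin(pmax(v, 0), 1)))
  }
  x <- png::readPNG(path, info = TRUE)
  depth <- attr(x, "info")$bit.depth %||% 8L
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x <- matrix(as.numeric(x), nrow(x), ncol(x))  # drop reader attributes
  if (kind == "auto") kind <- if (depth == 16L) "labeled" else "binary"
  switch(kind,
    labeled = labeled_mask(round(x * 65535)),
    binary = binary_mask(matrix(as.integer(round(x * (2^depth - 1)) > 0),
                                nrow(x), ncol(x))),
    probability = probability_mask(x))
}

#' Tile an image for sub-image inference
#'
#' Computes a grid of square tile origins that covers the image, with a
#' fixed overlap between neighbouring tiles. Tiles at the lower/right
#' border are clamped inside the image bounds, so all tiles have the full
#' tile size. If the tile does not fit the image at all, a single
#' full-image tile is returned with a warning.
#'
#' @param img An [rgb_image()] (or any object with `dim()` of length >= 2).
#' @param tile_size Tile side length in px (>= 32).
#' @param overlap Overlap between adjacent tiles in px (< `tile_size`).
#' @return A `tile_grid`: list with `origins` (n x 2 matrix of 1-based
#'   `(row, col)` origins), `tile_h`, `tile_w` and `shape`.
#' @examples
#' g <- tile_image(rgb_image(array(0, c(512, 512, 3))), 256, 128)
#' nrow(g$origins)  # 9
#' @export
tile_image <- function(img, tile_size, overlap = 0L) {
  stopifnot(tile_size >= 32, overlap >= 0, overlap < tile_size)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (tile_size > min(h, w)) {
    warning("tile size ", tile_size, " exceeds image extent ", h, "x", w,
            "; using a single full-image tile", call. = FALSE)
    return(structure(list(origins = matrix(c(1L, 1L), 1),
                          tile_h = h, tile_w = w, shape = c(h, w),
                          tile_size = tile_size, overlap = overlap),
                     class = "tile_grid"))
  }
  stride <- tile_size - overlap
  starts <- function(n) {
    s <- seq.int(1L, n - tile_size + 1L, by = stride)
    if (s[length(s)] + tile_size - 1L < n) s <- c(s, n - tile_size + 1L)
    s
  }
  sr <- starts(h); sc <- starts(w)
  origins <- cbind(rep(sr, times = length(sc)),
                   rep(sc, each = length(sr)))
  structure(list(origins = origins, tile_h = tile_size, tile_w = tile_size,
                 shape = c(h, w), tile_size = tile_size, overlap = overlap),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %d x %d over %d x %d (overlap %d)\n",
              nrow(x$origins), x$tile_h, x$tile_w, x$shape[1], x$shape[2],
              x$overlap))
  invisible(x)
}

# internal: extract tile i of a grid from an image array or matrix
extract_tile <- function(img, grid, i) {
  o <- grid$origins[i, ]
  rows <- o[1]:(o[1] + grid$tile_h - 1L)
  cols <- o[2]:(o[2] + grid$tile_w - 1L)
  if (length(dim(img)) == 3L) unclass(img)[rows, cols, , drop = FALSE]
  else img[rows, cols, drop = FALSE]
}

#' Stitch per-tile probability masks back to slide scale
#'
#' Overlapping pixels receive the arithmetic mean of all contributing
#' tiles, so tiles that agree are reproduced exactly.
#'
#' @param tiles List of `list(origin = c(row, col), mask = matrix)` pairs.
#' @param shape Target `c(H, W)`.
#' @return A [probability_mask()].
#' @export
stitch_probability <- function(tiles, shape) {
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  for (t in tiles) {
    m <- as.matrix(t$mask)
    o <- t$origin
    rows <- o[1]:(o[1] + nrow(m) - 1L)
    cols <- o[2]:(o[2] + ncol(m) - 1L)
    acc[rows, cols] <- acc[rows, cols] + m
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  if (any(cnt == 0))
    stop("internal error: tiles do not cover the full image", call. = FALSE)
  probability_mask(acc / cnt)
}

#' Resize images and masks
#'
#' Images and probability masks are resized with bilinear interpolation;
#' binary and labeled masks with nearest-neighbour sampling so labels are
#' never mixed.
#'
#' @param x An [rgb_image()] or mask.
#' @param h,w Target size in px.
#' @return Object of the same class at the new size.
#' @export
resize_image <- function(x, h, w) {
  rgb_image(cpp_resize_bilinear(unclass(x), h, w))
}

#' @rdname resize_image
#' @export
resize_mask <- function(x, h, w) {
  if (inherits(x, "probability_mask")) {
    cube <- array(as_plain(x), dim = c(dim(x), 1L))
    return(probability_mask(clip01(cpp_resize_bilinear(cube, h, w)[, , 1])))
  }
  out <- cpp_resize_nearest(as_plain(x), h, w)
  if (inherits(x, "binary_mask")) binary_mask(out) else labeled_mask(out)
}
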