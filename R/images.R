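#' Image and mask containers
#'
#' Lightweight S3 containers shared by all pipeline stages. An `rgb_image`
#' is a numeric `H x W x 3` array with 8-bit intensities in `[0, 255]`
#' (channel order red, green, blue); coordinates are `(row, col)`,
#' row-major with origin at the top-left pixel. Masks are `H x W`
#' matrices: a `probability_mask` holds reals in `[0, 1]`, a
#' `binary_mask` holds 0/1 integers, and a `labeled_mask` holds
#' non-negative integers where 0 is background and labels run gaplessly
#' from 1 to `n_components(x)`.
#'
#' @param x For `rgb_image`, an `H x W x 3` numeric array in `[0, 255]`
#'   or an `H x W` matrix (replicated to three channels). For the mask
#'   constructors, an `H x W` numeric matrix.
#' @return An object of the corresponding class.
#' @examples
#' img <- rgb_image(array(255, dim = c(4, 4, 3)))
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' n_components(labeled_mask(matrix(0L, 3, 3)))
#' @export
rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an rgb_image must be an H x W x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("image dimensions must be at least 1 x 1", call. = FALSE)
  x <- round(pmin(pmax(x, 0), 255))  # 8-bit contract
  storage.mode(x) <- "double"
  structure(x, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
rgba_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 4L)
    stop("an rgba_image must be an H x W x 4 array", call. = FALSE)
  x <- pmin(pmax(x, 0), 255)
  storage.mode(x) <- "double"
  structure(x, class = "rgba_image")
}

#' @rdname rgb_image
#' @export
probability_mask <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("probability values must lie in [0, 1]", call. = FALSE)
  structure(x, class = "probability_mask")
}

#' @rdname rgb_image
#' @export
binary_mask <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("a binary mask may only contain 0 and 1", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, class = "binary_mask")
}

#' @rdname rgb_image
#' @export
labeled_mask <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (anyNA(x) || any(x < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  k <- if (any(x > 0L)) max(x) else 0L
  present <- sort(unique(x[x > 0L]))
  if (length(present) && !identical(present, seq_len(k)))
    stop("labels must be exactly 1..K with no gaps", call. = FALSE)
  structure(x, class = "labeled_mask", n_components = k)
}

#' @rdname rgb_image
#' @export
n_components <- function(x) {
  k <- attr(x, "n_components")
  if (is.null(k)) k <- length(setdiff(unique(as.integer(x)), 0L))
  as.integer(k)
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, intensity range [%.0f, %.0f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.rgba_image <- function(x, ...) {
  cat(sprintf("<rgba_image> %d x %d px\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.probability_mask <- function(x, ...) {
  cat(sprintf("<probability_mask> %d x %d px, mean %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d px, %d components\n",
              nrow(x), ncol(x), n_components(x)))
  invisible(x)
}

#' @export
plot.rgb_image <- function(x, ...) {
  op <- par(mar = c(0, 0, 0, 0)); on.exit(par(op))
  plot(NA, xlim = c(0, ncol(x)), ylim = c(0, nrow(x)), asp = 1,
       axes = FALSE, xlab = "", ylab = "")
  rasterImage(unclass(x) / 255, 0, 0, ncol(x), nrow(x), ...)
  invisible(x)
}

#' @export
plot.probability_mask <- function(x, ...) {
  op <- par(mar = c(0, 0, 0, 0)); on.exit(par(op))
  image(t(x)[, nrow(x):1], col = gray(seq(0, 1, length.out = 64)),
        axes = FALSE, asp = nrow(x) / ncol(x), ...)
  invisible(x)
}

# internal: strip class, return plain array/matrix
as_plain <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
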