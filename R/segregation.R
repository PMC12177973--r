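#' Segregation settings
#'
#' Defaults follow the tissue-segregation stage contract: the tissue
#' probability mask is binarized at 0.8, components are labelled with
#' 8-connectivity, and components smaller than 20 px are dropped as
#' staining artifacts.
#'
#' @param threshold Probability threshold in (0, 1); pixels with
#'   probability `>= threshold` become foreground.
#' @param min_area Minimum component area in px; smaller components are
#'   removed and the remaining labels compacted.
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return A `segregation_config` list.
#' @export
segregation_config <- function(threshold = 0.8, min_area = 20L,
                               connectivity = 8L) {
  stopifnot(threshold > 0, threshold < 1, min_area >= 0,
            connectivity %in% c(4L, 8L))
  structure(list(threshold = threshold, min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity)),
            class = "segregation_config")
}

#' Segregate disconnected tissue pieces
#'
#' Binarizes a tissue probability mask, labels connected components in
#' first-encounter raster-scan order, removes components below the area
#' threshold and compacts the surviving labels to `1..K`.
#'
#' @param prob A [probability_mask()] (values in `[0, 1]`).
#' @param cfg A [segregation_config()].
#' @return A [labeled_mask()]; `n_components()` gives the number of
#'   surviving tissue pieces.
#' @examples
#' p <- probability_mask(matrix(0.9, 8, 8))
#' n_components(segregate(p))
#' @export
segregate <- function(prob, cfg = segregation_config()) {
  stopifnot(inherits(cfg, "segregation_config"))
  m <- as.matrix(prob)
  if (any(m < 0 | m > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  fg <- matrix(as.integer(m >= cfg$threshold), nrow(m), ncol(m))
  lab <- cpp_label_components(fg, cfg$connectivity)
  k <- attr(lab, "n_components")
  if (k == 0L) return(labeled_mask(lab))
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(areas >= cfg$min_area)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  labeled_mask(out)
}

#' Count connected components of a binary mask
#'
#' @param mask A [binary_mask()] (or 0/1 matrix).
#' @param connectivity 4 or 8.
#' @return Integer component count.
#' @export
count_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- as.matrix(mask)
  storage.mode(m) <- "integer"
  attr(cpp_label_components(m, as.integer(connectivity)), "n_components")
}

#' Write each segregated component as a cropped image
#'
#' @param img An [rgb_image()] aligned with `labels`.
#' @param labels A [labeled_mask()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_component_crops <- function(img, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_len(n_components(labels))) {
    pos <- which(labels == k, arr.ind = TRUE)
    rr <- range(pos[, 1]); cc <- range(pos[, 2])
    crop <- rgb_image(unclass(img)[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE])
    p <- file.path(dir, sprintf("component_%d.png", k))
    write_image(crop, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
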