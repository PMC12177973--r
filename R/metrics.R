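#' Segmentation overlap: Intersection over Union
#'
#' `|P & G| / (|P | G|)`. When both masks are empty the two methods agree
#' perfectly and the IoU is defined as 1.
#'
#' @param pred,gold [binary_mask()] objects (or 0/1 matrices) of equal
#'   size.
#' @return Ratio in `[0, 1]`.
#' @export
mask_iou <- function(pred, gold) {
  p <- as.matrix(pred); g <- as.matrix(gold)
  if (!identical(dim(p), dim(g)))
    stop("mask dimensions differ", call. = FALSE)
  uni <- sum(p == 1L | g == 1L)
  if (uni == 0) return(1)
  sum(p == 1L & g == 1L) / uni
}

# Boundary pixel coordinates (rows of (row, col)); boundary = foreground
# pixel with at least one background 4-neighbour, image border counting
# as background.
boundary_points <- function(mask) {
  m <- as.matrix(mask)
  storage.mode(m) <- "integer"
  which(cpp_boundary_mask(m) == 1L, arr.ind = TRUE)
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric sup-inf Euclidean distance between the boundary pixel sets
#' of the two masks.
#'
#' @inheritParams mask_iou
#' @return Distance in px; `NA` with a warning if either mask is empty.
#' @export
hausdorff_distance <- function(pred, gold) {
  bp <- boundary_points(pred); bg <- boundary_points(gold)
  if (nrow(bp) == 0 || nrow(bg) == 0) {
    warning("Hausdorff distance undefined for an empty mask", call. = FALSE)
    return(NA_real_)
  }
  cpp_hausdorff(bp, bg)
}

#' Perimeter ratio
#'
#' `|boundary(P)| / |boundary(G)|` with the same boundary-pixel-count
#' convention for both masks; flags over- (ratio > 1) and under-
#' segmentation (ratio < 1).
#'
#' @inheritParams mask_iou
#' @return Non-negative ratio; `NA` with a warning when `gold` has an
#'   empty boundary.
#' @export
perimeter_ratio <- function(pred, gold) {
  np <- nrow(boundary_points(pred)); ng <- nrow(boundary_points(gold))
  if (ng == 0) {
    warning("perimeter ratio undefined: gold boundary is empty",
            call. = FALSE)
    return(NA_real_)
  }
  np / ng
}

#' Connected-component count difference
#'
#' `|N(P) - N(G)|` under the chosen connectivity; captures over- and
#' under-segmentation of disconnected tissue.
#'
#' @inheritParams mask_iou
#' @param connectivity 4 or 8.
#' @return Non-negative integer.
#' @export
comp_diff <- function(pred, gold, connectivity = 8L) {
  p <- as.matrix(pred); g <- as.matrix(gold)
  if (!identical(dim(p), dim(g)))
    stop("mask dimensions differ", call. = FALSE)
  abs(count_components(p, connectivity) - count_components(g, connectivity))
}

#' Structural similarity index for RGB images
#'
#' Dense sliding-window SSIM with an 11 x 11 Gaussian window
#' (sigma = 1.5) and the conventional stability constants
#' `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` with `L = 255`, computed per
#' channel and averaged over windows and channels.
#'
#' @param x,y [rgb_image()] objects of equal size.
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 Stability constants relative to the dynamic range.
#' @return SSIM score (1 for identical images).
#' @export
ssim_score <- function(x, y, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(x), dim(y)))
    stop("image dimensions differ", call. = FALSE)
  L <- 255
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  xs <- unclass(x); ys <- unclass(y)
  per_ch <- vapply(1:3, function(ch) {
    a <- array(xs[, , ch], c(dim(xs)[1:2], 1L))
    b <- array(ys[, , ch], c(dim(ys)[1:2], 1L))
    mu_a <- cpp_gaussian_blur(a, sigma)
    mu_b <- cpp_gaussian_blur(b, sigma)
    s_aa <- cpp_gaussian_blur(a * a, sigma) - mu_a^2
    s_bb <- cpp_gaussian_blur(b * b, sigma) - mu_b^2
    s_ab <- cpp_gaussian_blur(a * b, sigma) - mu_a * mu_b
    m <- ((2 * mu_a * mu_b + c1) * (2 * s_ab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2))
    mean(m)
  }, numeric(1))
  mean(per_ch)
}

#' Mutual information between two images
#'
#' Converts both images to grayscale luma, bins intensities into a joint
#' 2-D histogram, normalises it to a joint probability distribution and
#' returns the mutual information in nats. Zero when either image is
#' constant (single occupied bin).
#'
#' @param x,y [rgb_image()] objects of equal size.
#' @param n_bins Bins per axis (default 64).
#' @return Mutual information in nats (non-negative).
#' @export
mutual_information <- function(x, y, n_bins = 64L) {
  if (!identical(dim(x)[1:2], dim(y)[1:2]))
    stop("image dimensions differ", call. = FALSE)
  gx <- to_gray(x); gy <- to_gray(y)
  bx <- pmin(floor(gx / 256 * n_bins), n_bins - 1L)
  by <- pmin(floor(gy / 256 * n_bins), n_bins - 1L)
  joint <- table(factor(bx, levels = 0:(n_bins - 1L)),
                 factor(by, levels = 0:(n_bins - 1L)))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  outer_pp <- outer(px, py)
  sum(p[pos] * log(p[pos] / outer_pp[pos]))
}

#' Multi-class Dice score
#'
#' Mean over classes of `2 |Ix=c & Iy=c| / (|Ix=c| + |Iy=c|)`. Classes
#' absent from both labelings are skipped (configurable via `classes`).
#'
#' @param x,y [labeled_mask()] objects (or integer matrices) of equal
#'   size.
#' @param classes Class ids to average over; defaults to all classes
#'   present in either labeling.
#' @return Score in `[0, 1]`.
#' @export
multiclass_dice <- function(x, y, classes = NULL) {
  xm <- as.matrix(x); ym <- as.matrix(y)
  if (!identical(dim(xm), dim(ym)))
    stop("labeling dimensions differ", call. = FALSE)
  if (is.null(classes))
    classes <- sort(unique(c(xm[xm > 0L], ym[ym > 0L])))
  if (length(classes) == 0L)
    stop("no classes to score", call. = FALSE)
  per <- vapply(classes, function(cl) {
    a <- xm == cl; b <- ym == cl
    denom <- sum(a) + sum(b)
    if (denom == 0) return(NA_real_)  # absent from both: skipped
    2 * sum(a & b) / denom
  }, numeric(1))
  mean(per, na.rm = TRUE)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table; 1 for identical partitions, about 0 for random
#' labelings.
#'
#' @param a,b Label vectors of equal length (>= 2).
#' @return ARI score.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b))
    stop("labelings must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least two elements", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions degenerate and identical
  (sum_ij - expected) / denom
}

#' Count segmented cells outside the tissue region
#'
#' An object counts as outside when its centroid (rounded to the nearest
#' pixel) falls on tissue background.
#'
#' @param cell_labels A [labeled_mask()] of segmented cells.
#' @param tissue A [binary_mask()] of the same size.
#' @return Integer count.
#' @export
cells_outside_tissue <- function(cell_labels, tissue) {
  lab <- as.matrix(cell_labels); tis <- as.matrix(tissue)
  if (!identical(dim(lab), dim(tis)))
    stop("mask dimensions differ", call. = FALSE)
  k <- n_components(cell_labels)
  out <- 0L
  for (cl in seq_len(k)) {
    pos <- which(lab == cl, arr.ind = TRUE)
    ctr <- round(colMeans(pos))
    ctr <- pmin(pmax(ctr, 1L), dim(lab))
    if (tis[ctr[1], ctr[2]] == 0L) out <- out + 1L
  }
  out
}

#' Extract fiducial markers from a vendor overlay image
#'
#' The vendor alignment tools export a layered image with red circles
#' over the H&E slide. Pixels within the predefined red range (R > 180,
#' G < 30, B < 30) are isolated, circles are detected on the isolated
#' component with the Hough transform, and each detected circle is
#' filled, yielding a binary marker mask comparable to network output.
#'
#' @param layered An [rgb_image()] with red circle overlays.
#' @param radius_range Circle radius search range in px.
#' @return A [binary_mask()].
#' @export
extract_overlay_markers <- function(layered, radius_range = c(3L, 9L)) {
  x <- unclass(layered)
  red <- x[, , 1] > 180 & x[, , 2] < 30 & x[, , 3] < 30
  mask <- matrix(0L, nrow(red), ncol(red))
  if (!any(red)) return(binary_mask(mask))
  det <- cpp_hough_circles(red * 255, as.integer(radius_range[1]),
                           as.integer(radius_range[2]), 0.1, 0.25,
                           min_dist = radius_range[1] + 1)
  if (nrow(det) > 0)
    for (i in seq_len(nrow(det)))
      mask <- draw_disc(mask, det[i, 1:2] + 1, det[i, 3])
  binary_mask(mask)
}

#' Full metric report for one prediction/gold pair
#'
#' @param pred,gold [binary_mask()] objects to compare.
#' @param pred_img,gold_img Optional [rgb_image()] pair for SSIM and
#'   mutual information.
#' @param connectivity Connectivity for the component difference.
#' @return A `metric_report` list with `iou`, `hausdorff`, `perim_ratio`,
#'   `comp_diff` and, when images are supplied, `ssim` and `mi`.
#' @export
metric_report <- function(pred, gold, pred_img = NULL, gold_img = NULL,
                          connectivity = 8L) {
  rep <- list(iou = mask_iou(pred, gold),
              hausdorff = suppressWarnings(hausdorff_distance(pred, gold)),
              perim_ratio = suppressWarnings(perimeter_ratio(pred, gold)),
              comp_diff = comp_diff(pred, gold, connectivity))
  if (!is.null(pred_img) && !is.null(gold_img)) {
    rep$ssim <- ssim_score(pred_img, gold_img)
    rep$mi <- mutual_information(pred_img, gold_img)
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else format(x[[nm]], digits = 4)))
  invisible(x)
}
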