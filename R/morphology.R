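# Object-level morphology descriptors used to characterise segmented
# cells (and to expose marker-derived false positives, which form their
# own morphology clusters).

# Cauchy-Crofton perimeter estimate from intercept counts along four
# line directions; unbiased for smooth shapes, unlike raw edge counting
# which overestimates curved boundaries by up to 4/pi.
crofton_perimeter <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- m
  n_h <- sum(pad[, -1] != pad[, -(w + 2)])
  n_v <- sum(pad[-1, ] != pad[-(h + 2), ])
  n_d1 <- sum(pad[-1, -1] != pad[-(h + 2), -(w + 2)])
  n_d2 <- sum(pad[-1, -(w + 2)] != pad[-(h + 2), -1])
  (pi / 2) * mean(c(n_h, n_v, n_d1 / sqrt(2), n_d2 / sqrt(2)))
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Morphology descriptors per segmented object
#'
#' Computes nine shape features for every labelled object: area (px^2),
#' perimeter (Crofton estimate, px), elongation (`1 - minor/major` axis
#' ratio of the fitted ellipse), eccentricity (from second central
#' moments), circularity (`4 pi A / P^2`), solidity (area over convex
#' hull area, hull taken over pixel corners so it is always in (0, 1]),
#' extent (area over bounding-box area), aspect ratio (bounding-box side
#' ratio, >= 1) and compactness (`P^2 / A`).
#'
#' @param labels A [labeled_mask()] with at least one object.
#' @return Data frame with one row per label and columns `label`, `area`,
#'   `perimeter`, `elongation`, `eccentricity`, `circularity`,
#'   `solidity`, `extent`, `aspect_ratio`, `compactness`, `centroid_row`,
#'   `centroid_col`.
#' @export
morphology_features <- function(labels) {
  k <- n_components(labels)
  if (k == 0L) stop("no labelled objects", call. = FALSE)
  lab <- as.matrix(labels)
  out <- lapply(seq_len(k), function(cl) {
    pos <- which(lab == cl, arr.ind = TRUE)
    area <- nrow(pos)
    rr <- range(pos[, 1]); cc <- range(pos[, 2])
    bh <- diff(rr) + 1L; bw <- diff(cc) + 1L
    sub <- matrix(0L, bh, bw)
    sub[cbind(pos[, 1] - rr[1] + 1L, pos[, 2] - cc[1] + 1L)] <- 1L
    per <- crofton_perimeter(sub)
    ctr <- colMeans(pos)
    dr <- pos[, 1] - ctr[1]; dc <- pos[, 2] - ctr[2]
    # 1/12 is the variance of a unit pixel; keeps thin objects non-degenerate
    mu20 <- mean(dr^2) + 1 / 12
    mu02 <- mean(dc^2) + 1 / 12
    mu11 <- mean(dr * dc)
    common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
    bnd <- which(cpp_boundary_mask(sub) == 1L, arr.ind = TRUE)
    corners <- rbind(bnd + rep(c(-0.5, -0.5), each = nrow(bnd)),
                     bnd + rep(c(-0.5, 0.5), each = nrow(bnd)),
                     bnd + rep(c(0.5, -0.5), each = nrow(bnd)),
                     bnd + rep(c(0.5, 0.5), each = nrow(bnd)))
    hull <- grDevices::chull(corners)
    hull_area <- polygon_area(corners[hull, , drop = FALSE])
    data.frame(label = cl, area = area, perimeter = per,
               elongation = 1 - minor / major,
               eccentricity = sqrt(max(1 - l2 / l1, 0)),
               circularity = 4 * pi * area / per^2,
               solidity = min(area / hull_area, 1),
               extent = area / (bh * bw),
               aspect_ratio = max(bh, bw) / min(bh, bw),
               compactness = per^2 / area,
               centroid_row = ctr[1], centroid_col = ctr[2])
  })
  do.call(rbind, out)
}

#' Standardise morphology features across objects
#'
#' Centres each feature to mean 0 and scales to standard deviation 1
#' (constant features become 0), the form used before projecting cells
#' into principal-component space.
#'
#' @param features Data frame from [morphology_features()].
#' @return Matrix of standardised features (label/centroid columns
#'   dropped).
#' @export
standardize_features <- function(features) {
  cols <- setdiff(names(features),
                  c("label", "centroid_row", "centroid_col"))
  m <- as.matrix(features[cols])
  sds <- apply(m, 2L, sd)
  centred <- sweep(m, 2L, colMeans(m))
  out <- sweep(centred, 2L, ifelse(sds > 0, sds, 1), `/`)
  out[, sds == 0] <- 0
  out
}
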