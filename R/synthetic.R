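#' Specification for a synthetic Visium-like slide
#'
#' Describes one simulated H&E thumbnail: a square frame of small circular
#' fiducial markers along the image border (individually jittered and
#' globally warped by a smooth elastic displacement field), one or more
#' textured tissue blobs over a light background, optional background
#' stain speckles, and a target marker-tissue overlap factor (the
#' fraction of markers whose centre falls inside tissue). The seed fully
#' determines the rendered sample.
#'
#' @param image_size Slide side length in px (>= 128).
#' @param markers_per_side Markers per frame side; the frame carries
#'   `4 * markers_per_side` circles.
#' @param marker_radius Nominal marker radius in px.
#' @param radius_jitter Uniform radius jitter half-width in px.
#' @param center_jitter Gaussian per-marker centre jitter SD in px.
#' @param deformation Elastic frame deformation amplitude in px (SD of a
#'   coarse random displacement grid, smoothly upsampled).
#' @param n_tissue_blobs Number of disjoint tissue pieces (0 for a blank
#'   background slide).
#' @param overlap_factor Target fraction of markers overlapping tissue,
#'   in `[0, 1]`.
#' @param stain_noise Density of faint background stain speckles (0 = a
#'   clean background).
#' @param seed Integer seed.
#' @return A `synthetic_spec` (validated list).
#' @export
synthetic_spec <- function(image_size = 256L, markers_per_side = 13L,
                           marker_radius = 5, radius_jitter = 0.5,
                           center_jitter = 0.5, deformation = 2,
                           n_tissue_blobs = 1L, overlap_factor = 0.1,
                           stain_noise = 0.02, seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               markers_per_side = as.integer(markers_per_side),
               marker_radius = marker_radius,
               radius_jitter = radius_jitter,
               center_jitter = center_jitter,
               deformation = deformation,
               n_tissue_blobs = as.integer(n_tissue_blobs),
               overlap_factor = overlap_factor,
               stain_noise = stain_noise,
               seed = as.integer(seed))
  if (spec$image_size < 128L)
    stop("image_size must be at least 128 px", call. = FALSE)
  if (spec$markers_per_side < 0L || spec$n_tissue_blobs < 0L ||
      spec$deformation < 0 || spec$radius_jitter < 0 || spec$stain_noise < 0)
    stop("counts, deformation and noise must be non-negative", call. = FALSE)
  if (spec$overlap_factor < 0 || spec$overlap_factor > 1)
    stop("overlap_factor must lie in [0, 1]", call. = FALSE)
  if (spec$overlap_factor > 0 && spec$n_tissue_blobs == 0L)
    stop("a positive overlap_factor requires at least one tissue blob",
         call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

# Smooth random field in roughly [-1, 1]: coarse Gaussian grid upsampled
# bilinearly and lightly blurred.
smooth_field <- function(size, coarse = 8L, sigma = size / 32) {
  g <- matrix(rnorm(coarse^2), coarse, coarse)
  f <- cpp_resize_bilinear(array(g, dim = c(coarse, coarse, 1L)), size, size)
  cpp_gaussian_blur(f, sigma)[, , 1]
}

# Ideal (undeformed) marker centres: 4 * n points around the frame square,
# each side traversed corner-to-corner excluding its end corner.
frame_centers <- function(size, n, margin) {
  lo <- margin; hi <- size - margin
  s <- seq(lo, hi, length.out = n + 1L)[seq_len(n)]
  rbind(cbind(lo, s),                      # top edge, left -> right
        cbind(s, hi),                      # right edge, top -> bottom
        cbind(hi, rev(s) + (hi - s[n])),   # bottom edge, right -> left
        cbind(rev(s) + (hi - s[n]), lo))   # left edge, bottom -> top
}

# Distance-to-centre matrix on a local window; used for disc/ring drawing.
draw_disc <- function(mask, center, radius, value = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(center[1] - radius - 1)); r1 <- min(h, ceiling(center[1] + radius + 1))
  c0 <- max(1L, floor(center[2] - radius - 1)); c1 <- min(w, ceiling(center[2] + radius + 1))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  sub <- mask[rr, cc]
  sub[d2 <= radius^2] <- value
  mask[rr, cc] <- sub
  mask
}

#' Generate one synthetic slide with full ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param render_markers If `FALSE`, the marker geometry and annotations
#'   are generated exactly as usual (the random draws are identical) but
#'   no marker ink is painted into the image. This provides a marker-free
#'   rendering of the *same* scene, the oracle for restoration quality.
#' @return A `synthetic_sample`: list with `image` ([rgb_image()]),
#'   `markers` (a `marker_annotation` with per-circle centres, radii,
#'   in-tissue flags, the rasterized union mask and the realised overlap
#'   factor), `tissue_mask` ([binary_mask()]) and `n_tissue_components`.
#' @examples
#' s <- generate_sample(synthetic_spec(image_size = 128, seed = 7))
#' s$markers$overlap_factor
#' @export
generate_sample <- function(spec, render_markers = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  size <- spec$image_size
  n_mark <- 4L * spec$markers_per_side
  margin <- max(12, round(0.08 * size))

  # --- marker geometry -----------------------------------------------------
  centers <- radii <- NULL
  if (n_mark > 0L) {
    centers <- frame_centers(size, spec$markers_per_side, margin)
    if (spec$center_jitter > 0)
      centers <- centers + matrix(rnorm(2L * n_mark, 0, spec$center_jitter),
                                  ncol = 2L)
    if (spec$deformation > 0) {
      dr <- smooth_field(size) ; dc <- smooth_field(size)
      sc <- spec$deformation / max(sd(dr), 1e-8)
      idx <- cbind(pmin(pmax(round(centers[, 1]), 1L), size),
                   pmin(pmax(round(centers[, 2]), 1L), size))
      centers <- centers + sc * cbind(dr[idx], dc[idx])
    }
    centers[, 1] <- pmin(pmax(centers[, 1], spec$marker_radius + 1),
                         size - spec$marker_radius)
    centers[, 2] <- pmin(pmax(centers[, 2], spec$marker_radius + 1),
                         size - spec$marker_radius)
    radii <- spec$marker_radius +
      runif(n_mark, -spec$radius_jitter, spec$radius_jitter)
  }

  # --- tissue mask ---------------------------------------------------------
  tissue <- matrix(0L, size, size)
  if (spec$n_tissue_blobs > 0L) {
    inner_r <- (size / 2 - margin - spec$marker_radius - 3)
    blob_center <- size / 2 + rnorm(2L, 0, size * 0.02)
    # leave room for the extra blobs when several pieces are requested
    blob_r <- if (spec$n_tissue_blobs > 1L) inner_r * runif(1, 0.3, 0.42)
              else inner_r * runif(1, 0.55, 0.75)
    band_centers <- NULL
    if (spec$overlap_factor > 0 && n_mark > 0L) {
      k <- max(1L, round(spec$overlap_factor * n_mark))
      start <- sample.int(n_mark, 1L)
      sel <- ((start - 1L + seq_len(k) - 1L) %% n_mark) + 1L
      band_centers <- centers[sel, , drop = FALSE]
    }
    # wobbly central blob from a thresholded smooth field
    fld <- smooth_field(size)
    rr <- matrix(seq_len(size), size, size)
    cc <- t(rr)
    d <- sqrt((rr - blob_center[1])^2 + (cc - blob_center[2])^2)
    blob <- (1 - d / blob_r) + 0.55 * fld > 0.12
    tissue[blob] <- 1L
    if (!is.null(band_centers)) {
      spacing <- (size - 2 * margin) / max(spec$markers_per_side, 1L)
      band_r <- max(spacing * 0.72, spec$marker_radius * 2)
      for (i in seq_len(nrow(band_centers)))
        tissue <- draw_disc(tissue, band_centers[i, ], band_r)
      # bridge the band to the central blob so the piece stays connected
      mid <- colMeans(band_centers)
      steps <- seq(0, 1, length.out = 24L)
      for (t in steps)
        tissue <- draw_disc(tissue, (1 - t) * mid + t * blob_center,
                            band_r * 0.6)
    }
    # the thresholded field can shed small islands; keep only the largest
    # connected piece so the main tissue is a single component
    lab <- cpp_label_components(tissue, 8L)
    if (attr(lab, "n_components") > 1L) {
      areas <- tabulate(lab[lab > 0L], nbins = attr(lab, "n_components"))
      tissue <- matrix(as.integer(lab == which.max(areas)), size, size)
    }
    # additional disjoint blobs, strictly inside the frame
    extra <- spec$n_tissue_blobs - 1L
    if (extra > 0L) {
      have <- tissue
      grown <- cpp_gaussian_blur(array(as.double(have), c(size, size, 1L)),
                                 3)[, , 1] > 1e-3
      for (b in seq_len(extra)) {
        r_b <- size * runif(1, 0.05, 0.075)
        for (try in 1:120) {
          if (try %% 30L == 0L) r_b <- r_b * 0.8  # shrink if space is tight
          ctr <- runif(2L, margin + r_b + spec$marker_radius + 3,
                       size - margin - r_b - spec$marker_radius - 3)
          rr0 <- max(1L, floor(ctr[1] - r_b - 4)); rr1 <- min(size, ceiling(ctr[1] + r_b + 4))
          cc0 <- max(1L, floor(ctr[2] - r_b - 4)); cc1 <- min(size, ceiling(ctr[2] + r_b + 4))
          if (!any(grown[rr0:rr1, cc0:cc1])) break
          ctr <- NULL
        }
        if (is.null(ctr)) next
        tissue <- draw_disc(tissue, ctr, r_b)
        grown <- cpp_gaussian_blur(array(as.double(tissue), c(size, size, 1L)),
                                   2)[, , 1] > 1e-3
      }
    }
  }
  tissue_mask <- binary_mask(tissue)
  n_comp <- count_components(tissue_mask, connectivity = 8L)

  # --- rendering -----------------------------------------------------------
  base <- c(250, 248, 246)
  img <- array(0, dim = c(size, size, 3L))
  bg_tex <- smooth_field(size, coarse = 16L, sigma = size / 64)
  for (ch in 1:3) img[, , ch] <- base[ch] + 2.5 * bg_tex +
    matrix(rnorm(size^2, 0, 1.2), size, size)

  if (spec$stain_noise > 0) {
    k <- rpois(1, spec$stain_noise * size^2 / 40)
    if (k > 0) {
      sp_center <- cbind(runif(k, 1, size), runif(k, 1, size))
      sp_r <- runif(k, 1, 3)
      speck <- matrix(0L, size, size)
      for (i in seq_len(k)) speck <- draw_disc(speck, sp_center[i, ], sp_r[i])
      alpha <- 0.5 * (cpp_gaussian_blur(array(as.double(speck),
                                              c(size, size, 1L)), 0.8)[, , 1])
      stain <- c(231, 203, 216)
      for (ch in 1:3) img[, , ch] <- (1 - alpha) * img[, , ch] +
        alpha * stain[ch]
    }
  }

  if (any(tissue > 0L)) {
    alpha <- cpp_gaussian_blur(array(as.double(tissue), c(size, size, 1L)),
                               1.2)[, , 1]
    tex <- 1 + 0.16 * smooth_field(size, coarse = 24L, sigma = size / 96)
    tint <- c(214, 153, 183)
    for (ch in 1:3) img[, , ch] <- (1 - alpha) * img[, , ch] +
      alpha * (tint[ch] * tex)
    # sparse darker nuclei-like specks inside tissue
    nn <- round(0.004 * sum(tissue))
    if (nn > 0) {
      pos <- which(tissue == 1L)
      pick <- sample(pos, nn)
      dark <- c(122, 78, 128)
      pr <- ((pick - 1L) %% size) + 1L
      pc <- ((pick - 1L) %/% size) + 1L
      for (ch in 1:3) img[cbind(pr, pc, ch)] <-
        0.4 * img[cbind(pr, pc, ch)] + 0.6 * dark[ch]
    }
  }

  marker_mask <- matrix(0L, size, size)
  if (n_mark > 0L) {
    ink <- c(73, 62, 70)
    for (i in seq_len(n_mark)) {
      ctr <- centers[i, ]; r <- radii[i]
      th <- max(1.4, 0.38 * r)
      r0 <- max(1L, floor(ctr[1] - r - 2)); r1 <- min(size, ceiling(ctr[1] + r + 2))
      c0 <- max(1L, floor(ctr[2] - r - 2)); c1 <- min(size, ceiling(ctr[2] + r + 2))
      rr_ <- r0:r1; cc_ <- c0:c1
      d <- sqrt(outer((rr_ - ctr[1])^2, (cc_ - ctr[2])^2, "+"))
      if (render_markers) {
        ring <- pmin(pmax((r + 0.5 - d), 0), 1) *
          pmin(pmax((d - (r - th) + 0.5), 0), 1)
        core <- pmin(pmax((r - th + 0.5 - d), 0), 1) * 0.45
        a <- pmin(ring + core, 1)
        for (ch in 1:3) img[rr_, cc_, ch] <- (1 - a) * img[rr_, cc_, ch] +
          a * ink[ch]
      }
      marker_mask <- draw_disc(marker_mask, ctr, r)
    }
  }

  in_tissue <- logical(0)
  if (n_mark > 0L) {
    idx <- cbind(pmin(pmax(round(centers[, 1]), 1L), size),
                 pmin(pmax(round(centers[, 2]), 1L), size))
    in_tissue <- tissue[idx] == 1L
  }
  circles <- data.frame(row = if (n_mark) centers[, 1] else numeric(0),
                        col = if (n_mark) centers[, 2] else numeric(0),
                        radius = if (n_mark) radii else numeric(0),
                        in_tissue = in_tissue)
  markers <- marker_annotation(circles, binary_mask(marker_mask))

  structure(list(image = rgb_image(pmin(pmax(img, 0), 255)),
                 markers = markers,
                 tissue_mask = tissue_mask,
                 n_tissue_components = n_comp,
                 spec = spec),
            class = "synthetic_sample")
}

#' Gold-standard marker annotations
#'
#' Bundles per-circle annotations (fractional centres in `(row, col)`
#' pixel coordinates, radii, in-tissue flags) with the rasterized union
#' mask. The overlap factor is the ratio of in-tissue markers to all
#' markers (0 when there are none); it drives difficulty-stratified
#' sampling during training.
#'
#' @param circles Data frame with columns `row`, `col`, `radius`,
#'   `in_tissue`.
#' @param mask [binary_mask()] with the rasterized circles.
#' @return A `marker_annotation`.
#' @export
marker_annotation <- function(circles, mask) {
  stopifnot(is.data.frame(circles),
            all(c("row", "col", "radius", "in_tissue") %in% names(circles)))
  f <- if (nrow(circles) == 0L) 0 else mean(circles$in_tissue)
  structure(list(circles = circles, mask = mask, overlap_factor = f),
            class = "marker_annotation")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_sample> %d px slide, %d markers ",
                     "(overlap %.2f), %d tissue component(s)\n"),
              nrow(x$image), nrow(x$markers$circles),
              x$markers$overlap_factor, x$n_tissue_components))
  invisible(x)
}

#' @export
print.marker_annotation <- function(x, ...) {
  cat(sprintf("<marker_annotation> %d circles, overlap factor %.3f\n",
              nrow(x$circles), x$overlap_factor))
  invisible(x)
}

#' Generate a difficulty-stratified corpus of synthetic slides
#'
#' Produces `n` slides whose realised marker overlap factors follow the
#' requested mixture of difficulty strata (hard: factor > 0.8, moderate:
#' factor in (0.3, 0.8], easy: factor < 0.3). Stratum counts use largest-
#' remainder rounding, so each requested proportion is met within one
#' sample.
#'
#' @param n Number of slides.
#' @param spec Template [synthetic_spec()]; per-slide seeds and overlap
#'   targets are derived from it.
#' @param mix Proportions `c(hard, moderate, easy)` summing to 1.
#' @return List of `synthetic_sample` objects.
#' @export
generate_corpus <- function(n, spec = synthetic_spec(),
                            mix = c(hard = 0, moderate = 0, easy = 1)) {
  stopifnot(n >= 0, length(mix) == 3L)
  if (abs(sum(mix) - 1) > 1e-8)
    stop("difficulty proportions must sum to 1", call. = FALSE)
  if (n == 0L) return(list())
  base <- floor(n * mix)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * mix - base
    base[order(-frac)[seq_len(rem)]] <- base[order(-frac)[seq_len(rem)]] + 1
  }
  targets <- list(hard = c(0.84, 0.95), moderate = c(0.42, 0.72),
                  easy = c(0.04, 0.2))
  bounds <- list(hard = c(0.8, 1), moderate = c(0.3, 0.8), easy = c(0, 0.3))
  out <- vector("list", n)
  i <- 0L
  for (s in c("hard", "moderate", "easy")) {
    for (j in seq_len(base[match(s, c("hard", "moderate", "easy"))])) {
      i <- i + 1L
      seed_i <- (spec$seed + 7919L * i) %% 2147483647L
      for (attempt in 1:8) {
        tgt <- targets[[s]][1] +
          (targets[[s]][2] - targets[[s]][1]) * ((attempt - 1) %% 4) / 4
        sp <- spec
        sp$overlap_factor <- tgt
        sp$seed <- as.integer((seed_i + attempt - 1L) %% 2147483647L)
        smp <- generate_sample(sp)
        f <- smp$markers$overlap_factor
        ok <- f > bounds[[s]][1] && f <= bounds[[s]][2]
        if (s == "easy") ok <- f < 0.3
        if (s == "hard") ok <- f > 0.8
        if (ok) break
      }
      out[[i]] <- smp
    }
  }
  out
}

#' Persist and reload a synthetic corpus
#'
#' Writes each sample as a PNG image, PNG marker/tissue masks, a JSON
#' circle annotation file and a YAML manifest recording the generating
#' spec and seed.
#'
#' @param corpus List of `synthetic_sample` objects.
#' @param dir Target directory (created if missing).
#' @return `dir` (for `save_corpus`); list of samples (for `load_corpus`).
#' @export
save_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(corpus)) {
    s <- corpus[[i]]
    stem <- sprintf("sample_%03d", i)
    write_image(s$image, file.path(dir, paste0(stem, ".png")))
    write_mask(s$markers$mask, file.path(dir, paste0(stem, "_markers.png")))
    write_mask(s$tissue_mask, file.path(dir, paste0(stem, "_tissue.png")))
    jsonlite::write_json(s$markers$circles,
                         file.path(dir, paste0(stem, "_circles.json")),
                         digits = NA)
    yaml::write_yaml(list(spec = unclass(s$spec),
                          n_tissue_components = s$n_tissue_components),
                     file.path(dir, paste0(stem, ".yaml")))
  }
  invisible(dir)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(dir) {
  stems <- sort(sub("\\.yaml$", "",
                    basename(list.files(dir, pattern = "^sample_\\d+\\.yaml$"))))
  lapply(stems, function(stem) {
    man <- yaml::read_yaml(file.path(dir, paste0(stem, ".yaml")))
    circles <- as.data.frame(jsonlite::read_json(
      file.path(dir, paste0(stem, "_circles.json")), simplifyVector = TRUE))
    if (nrow(circles) == 0L)
      circles <- data.frame(row = numeric(0), col = numeric(0),
                            radius = numeric(0), in_tissue = logical(0))
    mm <- read_mask(file.path(dir, paste0(stem, "_markers.png")), "binary")
    structure(list(image = read_image(file.path(dir, paste0(stem, ".png"))),
                   markers = marker_annotation(circles, mm),
                   tissue_mask = read_mask(
                     file.path(dir, paste0(stem, "_tissue.png")), "binary"),
                   n_tissue_components = man$n_tissue_components,
                   spec = do.call(synthetic_spec, man$spec)),
              class = "synthetic_sample")
  })
}
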