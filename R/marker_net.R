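#' Network architecture settings
#'
#' The marker segmentation network halves the spatial resolution four
#' times while widening the channels 3 -> 32 -> 64 -> 128 -> 256, then
#' mirrors back down 256 -> 128 -> 64 -> 32 -> 16. Downsampling uses 4x4
#' stride-2 convolutions; refinement convolutions are 3x3 stride 1; the
#' head is a 4x4 stride-1 convolution over the 19-channel map formed by
#' concatenating the 16 learned output channels with the 3 input
#' channels. Instance normalisation (no affine parameters) follows every
#' convolution except in the first encoder block and the bottleneck.
#'
#' @param widths_enc Encoder channel widths (default `c(32, 64, 128, 256)`).
#' @param widths_dec Decoder channel widths (default `c(128, 64, 32, 16)`).
#' @param dropout Dropout rate applied in encoder blocks 2-4 and decoder
#'   blocks 1-2 during training.
#' @return A `net_config` list. `output_channels` records the 19-channel
#'   pre-head map and the single-channel output.
#' @export
net_config <- function(widths_enc = c(32L, 64L, 128L, 256L),
                       widths_dec = c(128L, 64L, 32L, 16L),
                       dropout = 0.5) {
  stopifnot(length(widths_enc) == 4L, length(widths_dec) == 4L,
            dropout >= 0, dropout < 1)
  structure(list(widths_enc = as.integer(widths_enc),
                 widths_dec = as.integer(widths_dec),
                 output_channels = c(pre_head = widths_dec[4] + 3L, head = 1L),
                 down_kernel = c(4L, 4L), down_stride = 2L,
                 refine_kernel = c(3L, 3L), refine_stride = 1L,
                 head_kernel = c(4L, 4L), head_stride = 1L,
                 dropout = dropout, normalization = "instance"),
            class = "net_config")
}

#' Training settings
#'
#' Adam with learning rate `1e-4`, `beta1 = 0.5`, `beta2 = 0.999`. The
#' faithful preset trains for 800 epochs; the desk-scale default is 200,
#' suited to small synthetic corpora on a CPU. Hard slides (overlap
#' factor > 0.8) are visited three times per epoch and moderate slides
#' (factor in (0.3, 0.8]) twice.
#'
#' @param epochs Training epochs (>= 1); `preset = "faithful"` sets 800.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size Gradient accumulation size (1 = plain stochastic).
#' @param tile_size Training/inference tile side in px (multiple of 16).
#' @param overlap Tile overlap at inference in px.
#' @param seed RNG seed controlling initialisation, sampling, dropout and
#'   augmentation.
#' @param hard_multiplier,moderate_multiplier Per-epoch repetition of
#'   hard/moderate slides.
#' @param preset `"desk"` (200 epochs) or `"faithful"` (800 epochs).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = NULL, lr = 1e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 1L, tile_size = 256L,
                         overlap = 32L, seed = 1L, hard_multiplier = 3L,
                         moderate_multiplier = 2L,
                         preset = c("desk", "faithful")) {
  preset <- match.arg(preset)
  if (is.null(epochs)) epochs <- if (preset == "faithful") 800L else 200L
  stopifnot(epochs >= 1, hard_multiplier >= 1, moderate_multiplier >= 1,
            tile_size %% 16L == 0L)
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap), seed = as.integer(seed),
                 hard_multiplier = as.integer(hard_multiplier),
                 moderate_multiplier = as.integer(moderate_multiplier),
                 preset = preset),
            class = "train_config")
}

#' Augmentation settings
#'
#' Default ranges: left-right and up-down flips each with probability
#' 0.5, isotropic scaling in `[0.8, 1.0]`, rotation in `[-10, +10]`
#' degrees, brightness scaling in `[0.5, 1.2]`, and Gaussian blur with
#' standard deviation drawn from `[0, 1]`. Geometric transforms are
#' applied identically to the image and its mask; photometric transforms
#' (brightness, blur) touch the image only.
#'
#' @param flip_lr,flip_ud Flip probabilities.
#' @param scale Length-2 scaling range.
#' @param rotation Length-2 rotation range in degrees.
#' @param brightness Length-2 brightness factor range.
#' @param blur_sigma Length-2 Gaussian blur sigma range in px.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_lr = 0.5, flip_ud = 0.5,
                           scale = c(0.8, 1.0), rotation = c(-10, 10),
                           brightness = c(0.5, 1.2), blur_sigma = c(0, 1)) {
  structure(list(flip_lr = flip_lr, flip_ud = flip_ud, scale = scale,
                 rotation = rotation, brightness = brightness,
                 blur_sigma = blur_sigma),
            class = "augment_config")
}

#' Classify slide difficulty from the marker overlap factor
#'
#' Hard slides have overlap factor > 0.8, moderate slides a factor in
#' (0.3, 0.8], easy slides a factor <= 0.3 (a factor of exactly 0.3 is
#' assigned to the easy class).
#'
#' @param annotation A `marker_annotation` or a numeric overlap factor.
#' @return One of `"hard"`, `"moderate"`, `"easy"`.
#' @export
classify_difficulty <- function(annotation) {
  f <- if (inherits(annotation, "marker_annotation"))
    annotation$overlap_factor else as.numeric(annotation)
  if (f > 0.8) "hard" else if (f > 0.3) "moderate" else "easy"
}

#' Difficulty-weighted epoch sampling plan
#'
#' Builds one epoch's visiting order over the corpus: hard slides appear
#' `hard_multiplier` times, moderate slides `moderate_multiplier` times,
#' easy slides once, shuffled by the current RNG state.
#'
#' @param corpus List of samples carrying `$markers` annotations.
#' @param cfg A [train_config()].
#' @return Integer vector of corpus indices.
#' @export
build_sampling_plan <- function(corpus, cfg = train_config()) {
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  reps <- vapply(corpus, function(s) {
    switch(classify_difficulty(s$markers),
           hard = cfg$hard_multiplier,
           moderate = cfg$moderate_multiplier,
           easy = 1L)
  }, integer(1))
  sample(rep.int(seq_along(corpus), reps))
}

#' Jointly augment an image and its mask
#'
#' @param img An [rgb_image()].
#' @param mask A [binary_mask()] aligned with `img`.
#' @param cfg An [augment_config()].
#' @return List with augmented `img` and `mask`.
#' @export
augment_pair <- function(img, mask, cfg = augment_config()) {
  x <- unclass(img); m <- as_plain(mask)
  h <- dim(x)[1]; w <- dim(x)[2]
  if (runif(1) < cfg$flip_lr) { x <- x[, w:1, , drop = FALSE]; m <- m[, w:1, drop = FALSE] }
  if (runif(1) < cfg$flip_ud) { x <- x[h:1, , , drop = FALSE]; m <- m[h:1, , drop = FALSE] }
  sc <- runif(1, cfg$scale[1], cfg$scale[2])
  th <- runif(1, cfg$rotation[1], cfg$rotation[2]) * pi / 180
  if (abs(sc - 1) > 1e-12 || abs(th) > 1e-12) {
    # inverse map: rotate by -th and scale by 1/sc about the image centre
    cr <- (h + 1) / 2; cc <- (w + 1) / 2
    a <- cos(th) / sc; b <- sin(th) / sc
    A <- rbind(c(a, -b, cr - a * cr + b * cc),
               c(b,  a, cc - b * cr - a * cc))
    bgfill <- median(x[c(1, h), , ])
    x <- cpp_warp_affine(x, A, h, w, 1L, bgfill)
    mm <- cpp_warp_affine(array(as.double(m), c(h, w, 1L)), A, h, w, 0L, 0)
    m <- matrix(as.integer(mm[, , 1] > 0.5), h, w)
  }
  br <- runif(1, cfg$brightness[1], cfg$brightness[2])
  x <- pmin(pmax(x * br, 0), 255)
  sg <- runif(1, cfg$blur_sigma[1], cfg$blur_sigma[2])
  if (sg > 0.05) x <- cpp_gaussian_blur(x, sg)
  list(img = rgb_image(x), mask = binary_mask(m))
}

#' Fit the fiducial marker segmentation network
#'
#' Trains the encoder-decoder on an annotated corpus with the combined
#' soft-Dice + focal loss, difficulty-weighted sampling and (optionally)
#' the full augmentation stack, using Adam. The run is deterministic
#' given `train$seed`.
#'
#' @param corpus List of samples: each needs `$image` ([rgb_image()]) and
#'   `$markers` (a `marker_annotation`).
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @param loss A [loss_config()].
#' @param augment An [augment_config()], or `NULL` to disable
#'   augmentation.
#' @param verbose Print the epoch loss every `verbose` epochs (0 = quiet).
#' @return A fitted `marker_net` with elements `params`, `loss_trace`
#'   (per-epoch mean training loss) and the four config objects. Methods:
#'   `print`, `summary`, `coef`, `plot` (loss trace), `predict`.
#' @export
fit_marker_net <- function(corpus, net = net_config(),
                           train = train_config(), loss = loss_config(),
                           augment = NULL, verbose = 0L) {
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  if (!any(vapply(corpus, function(s) sum(s$markers$mask) > 0, logical(1))))
    stop("corpus has no slide with annotated markers", call. = FALSE)
  fit_segnet(corpus, target = "markers", net = net, train = train,
             loss = loss, augment = augment, verbose = verbose,
             class = "marker_net")
}

# Shared training loop for the marker network and the tissue saliency
# network; `target` selects the gold mask from each corpus entry.
fit_segnet <- function(corpus, target, net, train, loss, augment, verbose,
                       class) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(train$seed)

  params <- unet_init(net$widths_enc, net$widths_dec)
  state <- adam_init(params)
  step <- 0L
  trace <- numeric(train$epochs)
  gold_of <- function(s) {
    if (target == "markers") s$markers$mask else s$tissue_mask
  }
  for (ep in seq_len(train$epochs)) {
    plan <- build_sampling_plan(corpus, train)
    ep_loss <- 0
    for (idx in plan) {
      s <- corpus[[idx]]
      img <- s$image; gold <- gold_of(s)
      if (!is.null(augment)) {
        au <- augment_pair(img, gold, augment)
        img <- au$img; gold <- au$mask
      }
      x <- unclass(img) / 255
      fw <- unet_forward(params, x, dropout = net$dropout, training = TRUE)
      g <- as_plain(gold)
      l <- total_loss(fw$prob, g, loss, soft = TRUE)
      if (!is.finite(l))
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      grads <- unet_backward(params, fw$cache, total_loss_grad(fw$prob, g, loss))
      step <- step + 1L
      up <- adam_step(params, grads, state, step, train$lr, train$beta1,
                      train$beta2)
      params <- up$params; state <- up$state
      ep_loss <- ep_loss + l
    }
    trace[ep] <- ep_loss / length(plan)
    if (verbose > 0 && ep %% verbose == 0)
      cat(sprintf("epoch %d/%d: loss %.4f\n", ep, train$epochs, trace[ep]))
  }
  structure(list(params = params, loss_trace = trace, net = net,
                 train = train, loss = loss, augment = augment),
            class = c(class, "segnet"))
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("<%s> encoder %s, decoder %s; %d epochs, final loss %.4f\n",
              class(x)[1],
              paste(x$net$widths_enc, collapse = "-"),
              paste(x$net$widths_dec, collapse = "-"),
              length(x$loss_trace), tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.segnet <- function(object, ...) {
  npar <- sum(vapply(object$params,
                     function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("%s with %d parameters\n", class(object)[1], npar))
  cat("encoder widths:", paste(object$net$widths_enc, collapse = ", "), "\n")
  cat("decoder widths:", paste(object$net$widths_dec, collapse = ", "), "\n")
  cat("pre-head channels:", object$net$output_channels["pre_head"], "\n")
  cat(sprintf("training: %d epochs, Adam(lr=%g, beta1=%g, beta2=%g), seed %d\n",
              object$train$epochs, object$train$lr, object$train$beta1,
              object$train$beta2, object$train$seed))
  invisible(object)
}

#' @export
coef.segnet <- function(object, ...) object$params

#' @export
plot.segnet <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}

#' @export
predict.marker_net <- function(object, newdata, ...) {
  predict_slide(newdata, object, ...)$prob
}

#' Tiled whole-slide marker inference
#'
#' Tiles the slide, runs the network on each tile, stitches the per-tile
#' probabilities (mean on overlaps) back to slide scale and thresholds.
#'
#' @param img An [rgb_image()].
#' @param model A fitted `marker_net`.
#' @param tile_size,overlap Tiling geometry in px; defaults come from the
#'   model's training config.
#' @param threshold Binarization threshold (default 0.5).
#' @return List with `prob` ([probability_mask()]) and `mask`
#'   ([binary_mask()]).
#' @export
predict_slide <- function(img, model, tile_size = NULL, overlap = NULL,
                          threshold = 0.5) {
  tile_size <- tile_size %||% model$train$tile_size
  overlap <- overlap %||% model$train$overlap
  d <- dim(img)
  x <- unclass(img) / 255
  grid <- suppressWarnings(tile_image(img, tile_size, overlap))
  tiles <- lapply(seq_len(nrow(grid$origins)), function(i) {
    tl <- extract_tile(x, grid, i)
    fw <- unet_forward(model$params, tl, training = FALSE)
    list(origin = grid$origins[i, ], mask = fw$prob)
  })
  prob <- stitch_probability(tiles, d[1:2])
  list(prob = prob, mask = binary_mask((as_plain(prob) >= threshold) * 1L))
}

#' Hough circle transform baseline for marker detection
#'
#' Classical non-learning baseline: Sobel edge detection, gradient-
#' directed centre voting over a radius range, and greedy non-maximum
#' suppression. Detected circles are returned as annotations whose union
#' mask can be scored against the gold standard.
#'
#' @param img An [rgb_image()].
#' @param radius_range Length-2 integer radius range in px.
#' @param sensitivity Minimum fraction of perimeter support for a
#'   detection, in (0, 1).
#' @param edge_rel Edge threshold relative to the maximum gradient.
#' @return A `marker_annotation` (with `in_tissue` set to `NA`).
#' @export
hough_baseline <- function(img, radius_range = c(3L, 9L),
                           sensitivity = 0.3, edge_rel = 0.18) {
  g <- to_gray(img)
  det <- cpp_hough_circles(g, as.integer(radius_range[1]),
                           as.integer(radius_range[2]), edge_rel,
                           sensitivity,
                           min_dist = sum(radius_range) / 2)
  mask <- matrix(0L, nrow(g), ncol(g))
  n <- nrow(det)
  if (n > 0) {
    for (i in seq_len(n))
      mask <- draw_disc(mask, det[i, 1:2] + 1, det[i, 3])
  }
  circles <- data.frame(row = if (n) det[, 1] + 1 else numeric(0),
                        col = if (n) det[, 2] + 1 else numeric(0),
                        radius = if (n) det[, 3] else numeric(0),
                        in_tissue = rep(NA, n))
  marker_annotation(circles, binary_mask(mask))
}

#' k-fold cross-validation split
#'
#' Shuffles the corpus into `k` groups of size differing by at most one;
#' each fold tests exactly one group and trains on the rest.
#'
#' @param corpus List (or its length) to split.
#' @param k Number of folds (default 12).
#' @param seed RNG seed for the shuffle.
#' @return List of `k` lists with `train` and `test` index vectors.
#' @export
crossval_split <- function(corpus, k = 12L, seed = 1L) {
  n <- if (is.numeric(corpus) && length(corpus) == 1L) corpus
       else length(corpus)
  if (n < k) stop("corpus size (", n, ") is smaller than k = ", k,
                  call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  grp <- sample(rep_len(seq_len(k), n))
  lapply(seq_len(k), function(i)
    list(train = which(grp != i), test = which(grp == i)))
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single archive holding the weights, all config
#' objects, the seed and the package version.
#'
#' @param model A fitted `marker_net` or `tissue_net`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "segnet"))
  payload <- list(model = model,
                  version = as.character(utils::packageVersion("stclean")))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  payload$model
}
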