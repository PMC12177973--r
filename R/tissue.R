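#' Tissue detection settings
#'
#' The detector resizes the slide to a small working size (default
#' 320 x 320), runs a saliency network, and upsamples the probability
#' map back to the original resolution. If the first pass finds only a
#' small tissue region (bounding box of probability > 0.5 smaller than
#' 100 x 100 px at original scale), the slide is reprocessed at the
#' 1000 x 1000 working size with the compact model variant, which
#' resolves finer structures.
#'
#' @param working_size First-pass working size in px.
#' @param small_working_size Second-pass working size for small tissue.
#' @param small_trigger Side length in px (original scale) below which
#'   the second pass is triggered.
#' @param variant Preferred model variant, `"standard"` or `"compact"`.
#' @return A `tissue_config` list.
#' @export
tissue_config <- function(working_size = 320L, small_working_size = 1000L,
                          small_trigger = 100L,
                          variant = c("standard", "compact")) {
  stopifnot(working_size > 0, small_working_size > 0, small_trigger > 0)
  structure(list(working_size = as.integer(working_size),
                 small_working_size = as.integer(small_working_size),
                 small_trigger = as.integer(small_trigger),
                 variant = match.arg(variant)),
            class = "tissue_config")
}

# Channel widths of the two saliency variants: much lighter than the
# marker network since tissue-vs-background is a coarse task.
tissue_net_widths <- function(variant) {
  if (variant == "compact")
    list(enc = c(4L, 8L, 16L, 32L), dec = c(16L, 8L, 4L, 4L))
  else
    list(enc = c(8L, 16L, 32L, 64L), dec = c(32L, 16L, 8L, 8L))
}

#' Fit the tissue saliency network
#'
#' Trains a light encoder-decoder (sharing the marker network's block
#' library, shallower widths) to separate tissue from background.
#' Training pairs are resized to the working size; inference follows the
#' same convention.
#'
#' @param corpus List of samples with `$image` and `$tissue_mask`.
#' @param variant `"standard"` or `"compact"`.
#' @param working_size Training resolution in px (rounded up to a
#'   multiple of 16 internally via reflective padding).
#' @param epochs,lr,seed Training-loop controls.
#' @param dropout Dropout rate during training.
#' @param verbose Print the epoch loss every `verbose` epochs.
#' @return A fitted `tissue_net` (a `segnet`; see [fit_marker_net()] for
#'   the available methods).
#' @export
fit_tissue_net <- function(corpus, variant = c("standard", "compact"),
                           working_size = 320L, epochs = 40L, lr = 1e-3,
                           seed = 1L, dropout = 0.1, verbose = 0L) {
  variant <- match.arg(variant)
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  wd <- tissue_net_widths(variant)
  net <- net_config(wd$enc, wd$dec, dropout = dropout)
  train <- train_config(epochs = epochs, lr = lr, seed = seed,
                        tile_size = 16L * ceiling(working_size / 16L))
  # saliency loss: balanced classes, gentler focus than the marker loss
  loss <- loss_config(alpha = 0.6, gamma = 2, lambda = 0.7)
  scaled <- lapply(corpus, function(s) {
    list(image = resize_image(s$image, working_size, working_size),
         tissue_mask = resize_mask(s$tissue_mask, working_size, working_size),
         markers = marker_annotation(
           data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), in_tissue = logical(0)),
           binary_mask(matrix(0L, working_size, working_size))))
  })
  model <- fit_segnet(scaled, target = "tissue", net = net, train = train,
                      loss = loss, augment = NULL, verbose = verbose,
                      class = "tissue_net")
  model$variant <- variant
  model$working_size <- as.integer(working_size)
  model
}

#' Detect tissue on a (restored) slide
#'
#' Runs the saliency backend at the configured working size and
#' upsamples the probability map to the original resolution. When the
#' first-pass tissue bounding box is smaller than the configured
#' trigger, the slide is rerun at the small-tissue working size with the
#' compact variant (if provided).
#'
#' @param img An [rgb_image()] (ideally marker-free).
#' @param model A fitted `tissue_net`, or a list
#'   `list(standard = , compact = )` with both variants.
#' @param cfg A [tissue_config()].
#' @return A `tissue_result`: list with `prob` ([probability_mask()] at
#'   original resolution), `blend` ([rgba_image()] with alpha
#'   proportional to the tissue probability), and `second_pass` (logical).
#' @export
detect_tissue <- function(img, model, cfg = tissue_config()) {
  models <- if (inherits(model, "tissue_net")) {
    stats::setNames(list(model), model$variant %||% "standard")
  } else model
  pick <- function(variant) models[[variant]] %||% models[[1]]

  run_pass <- function(variant, size) {
    m <- pick(variant)
    small <- resize_image(img, size, size)
    fw <- unet_forward(m$params, unclass(small) / 255, training = FALSE)
    resize_mask(probability_mask(clip01(fw$prob)), nrow(img), ncol(img))
  }

  prob <- run_pass(cfg$variant, cfg$working_size)
  second <- FALSE
  fg <- which(as_plain(prob) > 0.5, arr.ind = TRUE)
  if (nrow(fg) > 0) {
    ext <- c(diff(range(fg[, 1])), diff(range(fg[, 2]))) + 1L
    if (all(ext < cfg$small_trigger)) {
      message("tissue extent ", ext[1], "x", ext[2], " px < ",
              cfg$small_trigger, "; rerunning at ",
              cfg$small_working_size, " with the compact variant")
      prob <- run_pass("compact", cfg$small_working_size)
      second <- TRUE
    }
  }
  structure(list(prob = prob, blend = blend_rgba(img, prob),
                 second_pass = second),
            class = "tissue_result")
}

#' @export
print.tissue_result <- function(x, ...) {
  cat(sprintf("<tissue_result> %d x %d px, mean prob %.3f%s\n",
              nrow(x$prob), ncol(x$prob), mean(x$prob),
              if (x$second_pass) " (small-tissue second pass)" else ""))
  invisible(x)
}

#' Otsu threshold baseline for tissue detection
#'
#' Grayscale conversion followed by an exhaustive 0-255 threshold search
#' maximising the inter-class variance; the darker (stained) class is
#' returned as foreground.
#'
#' @param img An [rgb_image()].
#' @return A [binary_mask()]; the chosen threshold is attached as
#'   attribute `"threshold"`.
#' @export
otsu_baseline <- function(img) {
  g <- round(to_gray(img))
  counts <- tabulate(g + 1L, nbins = 256L)
  n <- sum(counts)
  if (sum(counts > 0) <= 1L) {
    warning("constant image; returning an empty mask", call. = FALSE)
    out <- binary_mask(matrix(0L, nrow(g), ncol(g)))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  levels <- 0:255
  best <- -1; best_t <- 0
  w_all <- n; mu_all <- sum(levels * counts)
  w0 <- 0; s0 <- 0
  for (t in 0:254) {
    w0 <- w0 + counts[t + 1L]
    s0 <- s0 + t * counts[t + 1L]
    w1 <- w_all - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- s0 / w0; mu1 <- (mu_all - s0) / w1
    between <- w0 * w1 * (mu0 - mu1)^2
    if (between > best) { best <- between; best_t <- t }
  }
  out <- binary_mask(matrix(as.integer(g <= best_t), nrow(g), ncol(g)))
  attr(out, "threshold") <- as.numeric(best_t)
  out
}

#' Blend an image with its tissue probability
#'
#' Copies the RGB channels and sets the alpha channel to
#' `round(255 * prob)`, visually highlighting detected tissue.
#'
#' @param img An [rgb_image()].
#' @param prob A [probability_mask()] of the same size.
#' @return An [rgba_image()].
#' @export
blend_rgba <- function(img, prob) {
  stopifnot(identical(dim(img)[1:2], dim(prob)))
  rgba_image(array(c(unclass(img), round(255 * as_plain(prob))),
                   dim = c(dim(img)[1:2], 4L)))
}
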