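#' Loss settings for marker segmentation training
#'
#' Houses the combined-loss hyperparameters: the focal class weight
#' `alpha = 0.95` and focusing exponent `gamma = 3`, the Dice/focal
#' mixing weight `lambda = 0.9`, the Dice smoothing term `epsilon = 1`,
#' and the 0.5 binarization threshold applied to predicted probabilities
#' when the (reported, hard) Dice loss is evaluated.
#'
#' @param alpha Focal class weight in `[0, 1]` for the marker class.
#' @param gamma Focal focusing exponent (>= 0).
#' @param lambda Dice weight in the total loss, in `[0, 1]`.
#' @param epsilon Dice smoothing factor (> 0).
#' @param threshold Binarization threshold for the hard Dice loss.
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.95, gamma = 3, lambda = 0.9,
                        epsilon = 1.0, threshold = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, lambda >= 0, lambda <= 1,
            epsilon > 0, threshold > 0, threshold < 1)
  structure(list(alpha = alpha, gamma = gamma, lambda = lambda,
                 epsilon = epsilon, threshold = threshold),
            class = "loss_config")
}

#' Dice loss
#'
#' `1 - (2|P \& G| + eps) / (|P| + |G| + eps)`. By default the prediction
#' is binarized at `cfg$threshold` first (the reported form); with
#' `soft = TRUE` the probabilities enter directly, which is the
#' differentiable relaxation used during training.
#'
#' @param pred Predicted probabilities (matrix or [probability_mask()]).
#' @param gold Gold-standard [binary_mask()] (or 0/1 matrix).
#' @param cfg A [loss_config()].
#' @param soft Use the differentiable soft relaxation.
#' @return Non-negative scalar.
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(m, m)  # 0
#' @export
dice_loss <- function(pred, gold, cfg = loss_config(), soft = FALSE) {
  p <- as.matrix(pred); g <- as.matrix(gold)
  stopifnot(identical(dim(p), dim(g)))
  if (!soft) p <- (p >= cfg$threshold) * 1
  1 - (2 * sum(p * g) + cfg$epsilon) / (sum(p) + sum(g) + cfg$epsilon)
}

#' Focal loss
#'
#' Pixel-mean focal loss with class weight `alpha` on the marker class
#' and focusing exponent `gamma`; reduces to `alpha`-weighted binary
#' cross-entropy at `gamma = 0`.
#'
#' @inheritParams dice_loss
#' @param clip Probability clipping bound for numerical safety.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(pred, gold, cfg = loss_config(), clip = 1e-7) {
  p <- clip01(as.matrix(pred), clip); g <- as.matrix(gold)
  stopifnot(identical(dim(p), dim(g)))
  -mean(cfg$alpha * g * (1 - p)^cfg$gamma * log(p) +
          (1 - cfg$alpha) * (1 - g) * p^cfg$gamma * log(1 - p))
}

#' Combined segmentation loss
#'
#' `lambda * dice + (1 - lambda) * focal`, the convex combination used
#' to train the marker network.
#'
#' @inheritParams dice_loss
#' @param soft Use the soft Dice relaxation (training form).
#' @return Non-negative scalar.
#' @export
total_loss <- function(pred, gold, cfg = loss_config(), soft = FALSE) {
  cfg$lambda * dice_loss(pred, gold, cfg, soft = soft) +
    (1 - cfg$lambda) * focal_loss(pred, gold, cfg)
}

# Analytic gradient of the training loss (soft Dice + focal) with respect
# to the predicted probabilities. Checked against finite differences in
# the test suite.
total_loss_grad <- function(pred, gold, cfg = loss_config(), clip = 1e-7) {
  p <- as.matrix(pred); g <- as.matrix(gold)
  n <- length(p)
  inter <- sum(p * g); uni <- sum(p) + sum(g)
  ddice <- -(2 * g * (uni + cfg$epsilon) - (2 * inter + cfg$epsilon)) /
    (uni + cfg$epsilon)^2
  pc <- clip01(p, clip)
  dfoc <- (cfg$alpha * g *
             (cfg$gamma * (1 - pc)^(cfg$gamma - 1) * log(pc) -
                (1 - pc)^cfg$gamma / pc) +
           (1 - cfg$alpha) * (1 - g) *
             (-cfg$gamma * pc^(cfg$gamma - 1) * log(1 - pc) +
                pc^cfg$gamma / (1 - pc))) / n
  dfoc[p <= clip | p >= 1 - clip] <- 0  # clipped region is flat
  cfg$lambda * ddice + (1 - cfg$lambda) * dfoc
}
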