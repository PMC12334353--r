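#' Training-objective configuration
#'
#' @param ssim_window Side length of the uniform local SSIM window (odd,
#'   >= 3).
#' @param ssim_k1,ssim_k2 SSIM stabilizing constants; the additive constants
#'   are `(k1 * L)^2` and `(k2 * L)^2` with dynamic range `L = 1`.
#' @param w_image,w_seg Combination weights of the image and segmentation
#'   losses.
#' @param eps Probability clamp applied before logarithms in the
#'   cross-entropy term.
#' @export
loss_config <- function(ssim_window = 11, ssim_k1 = 0.01, ssim_k2 = 0.03,
                        w_image = 1, w_seg = 1, eps = 1e-6) {
  stopifnot(ssim_window >= 3, ssim_window %% 2 == 1,
            ssim_k1 > 0, ssim_k2 > 0, w_image >= 0, w_seg >= 0,
            eps > 0, eps < 0.5)
  structure(list(ssim_window = as.integer(ssim_window),
                 ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 w_image = w_image, w_seg = w_seg, eps = eps),
            class = "loss_config")
}

#' Structural similarity between two images
#'
#' Mean over all complete `w x w` windows of the local SSIM map computed
#' with window-local means, variances and covariance and the standard
#' constants (dynamic range 1). Symmetric in its arguments; bounded by 1
#' in absolute value; `ssim(x, x) = 1`.
#'
#' @param x,y Images of identical size with values in `[0, 1]`.
#' @param cfg A [loss_config()].
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, cfg = loss_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop(sprintf("image shapes differ: %dx%d vs %dx%d",
                 nrow(x), ncol(x), nrow(y), ncol(y)))
  w <- cfg$ssim_window
  if (nrow(x) < w || ncol(x) < w)
    stop("images smaller than the SSIM window")
  cpp_ssim(x, y, w, cfg$ssim_k1^2, cfg$ssim_k2^2)
}

#' Image reconstruction loss: 1 - SSIM
#' @inheritParams ssim
#' @return Non-negative scalar, zero iff the SSIM is 1.
#' @export
image_loss <- function(x, y, cfg = loss_config()) 1 - ssim(x, y, cfg)

#' Segmentation loss: cross-entropy + Dice + false-positive penalty
#'
#' `L = -mean(y log x + (1-y) log(1-x)) + (1 - 2 sum(x y) / (sum x + sum y))
#'  + mean(x (1-y))` with probabilities clamped to `[eps, 1-eps]` inside the
#' logarithms and a small additive smoothing (1e-6) in the Dice ratio to
#' guard empty masks. All three terms are non-negative and the loss is
#' minimized as `x` approaches `y`.
#'
#' @param x Predicted probabilities in `[0, 1]`.
#' @param y Binary ground-truth mask.
#' @param cfg A [loss_config()].
#' @export
seg_loss <- function(x, y, cfg = loss_config()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("prediction and mask lengths differ")
  if (any(x < 0 | x > 1)) stop("predicted probabilities outside [0, 1]")
  if (!all(y %in% c(0, 1))) stop("mask is not binary")
  xc <- pmin(pmax(x, cfg$eps), 1 - cfg$eps)
  bce <- -mean(y * log(xc) + (1 - y) * log(1 - xc))
  s <- 1e-6
  dice_term <- 1 - 2 * (sum(x * y) + s) / (sum(x) + sum(y) + s)
  fp <- mean(x * (1 - y))
  bce + dice_term + fp
}

#' Combined training loss
#' @param image_loss,seg_loss Scalar loss components.
#' @param cfg A [loss_config()] supplying the weights.
#' @export
total_loss <- function(image_loss, seg_loss, cfg = loss_config()) {
  cfg$w_image * image_loss + cfg$w_seg * seg_loss
}
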