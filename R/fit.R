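#' Training configuration
#'
#' @param epochs Number of passes over all frames.
#' @param lr_init,lr_min Initial and final learning rate of the cosine
#'   annealing schedule.
#' @param grokfast_alpha EMA decay of the gradient low-pass filter.
#' @param grokfast_lambda Amplification of the slow gradient component;
#'   0 disables the filter.
#' @param frames_per_step Whole frames per optimization step (the image loss
#'   is windowed, so batches are whole frames rather than pixel subsets).
#' @param seed Master seed: fans out to initialization and frame shuffling.
#' @export
train_config <- function(epochs = 500, lr_init = 1e-3, lr_min = 1e-6,
                         grokfast_alpha = 0.98, grokfast_lambda = 2,
                         frames_per_step = 4, seed = 1) {
  stopifnot(epochs >= 1, lr_min < lr_init, lr_min > 0,
            grokfast_alpha > 0, grokfast_alpha < 1, grokfast_lambda >= 0,
            frames_per_step >= 1)
  structure(list(epochs = as.integer(epochs), lr_init = lr_init,
                 lr_min = lr_min, grokfast_alpha = grokfast_alpha,
                 grokfast_lambda = grokfast_lambda,
                 frames_per_step = as.integer(frames_per_step),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine annealing learning-rate schedule
#'
#' `lr(e) = lr_min + (lr_init - lr_min) (1 + cos(pi e / epochs)) / 2`,
#' monotone non-increasing from `lr_init` at epoch 0 to `lr_min` at the
#' final epoch.
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [train_config()].
#' @export
cosine_lr <- function(epoch, cfg) {
  cfg$lr_min + 0.5 * (cfg$lr_init - cfg$lr_min) * (1 + cos(pi * epoch / cfg$epochs))
}

#' Gradient EMA low-pass filter
#'
#' The EMA variant of gradient filtering used to accelerate convergence:
#' `ema <- alpha * ema + (1 - alpha) * grad` and the filtered gradient is
#' `grad + lambda * ema`. With `lambda = 0` the gradients pass through
#' unchanged; for a constant gradient stream the filtered gradient
#' approaches `(1 + lambda) * grad`.
#'
#' @param grad Gradient (numeric vector/matrix, or list thereof).
#' @param ema_state Matching EMA state; `NULL` initializes at zero.
#' @param cfg A [train_config()] supplying `grokfast_alpha` and
#'   `grokfast_lambda`.
#' @return List with elements `grad` (filtered) and `ema` (updated state).
#' @export
grokfast_filter <- function(grad, ema_state = NULL, cfg = train_config()) {
  a <- cfg$grokfast_alpha; l <- cfg$grokfast_lambda
  if (is.list(grad)) {
    if (is.null(ema_state)) ema_state <- lapply(grad, function(g) g * 0)
    ema <- mapply(function(g, e) a * e + (1 - a) * g, grad, ema_state,
                  SIMPLIFY = FALSE)
    filt <- mapply(function(g, e) g + l * e, grad, ema, SIMPLIFY = FALSE)
    return(list(grad = filt, ema = ema))
  }
  if (is.null(ema_state)) ema_state <- grad * 0
  ema <- a * ema_state + (1 - a) * grad
  list(grad = grad + l * ema, ema = ema)
}

#' Fit an INR to a set of rotational-sweep frames
#'
#' Trains one coordinate network on one frame set: every step draws
#' `frames_per_step` whole frames, maps their pixels to normalized world
#' coordinates, evaluates the network, and minimizes
#' `w_image * (1 - SSIM) + w_seg * (BCE + Dice + FP)` with Adam, cosine
#' annealing and gradient EMA filtering. Fully reproducible given
#' `train_cfg$seed` (single-threaded BLAS assumed for bit reproducibility).
#'
#' @param frames A [frame_set()].
#' @param inr_cfg An [inr_config()].
#' @param loss_cfg A [loss_config()]; set `w_seg = 0` to train without
#'   masks.
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List of class `inr_fit` with elements `model` (the trained
#'   [inr_model]) and `log` (per-epoch data frame: epoch, lr, loss_image,
#'   loss_seg, total).
#' @export
fit_inr <- function(frames, inr_cfg = inr_config(), loss_cfg = loss_config(),
                    train_cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(frames, "frame_set"))
  geom <- frames$geom
  scale <- coord_scale(geom)
  local_seed(train_cfg$seed)

  model <- inr_init(inr_cfg, scale)

  # per-frame normalized pixel coordinates, column-major raster order
  px <- frame_pixel_grid(geom)
  coord_list <- lapply(frames$angles_deg, function(a)
    normalize_coords(frame_to_world(geom, a, px$rows, px$cols), scale))
  img_list <- lapply(frames$intensity, as.vector)
  mask_list <- lapply(frames$mask, as.vector)
  data <- cpp_make_train_data(coord_list, img_list, mask_list,
                              inr_cfg$pe_bands, geom$rows, geom$cols)

  n_frames <- length(frames$angles_deg)
  fps <- min(train_cfg$frames_per_step, n_frames)
  epochs <- train_cfg$epochs

  # schedule and frame shuffles drawn up front so all randomness is R's
  lrs <- cosine_lr(seq_len(epochs) - 1, train_cfg)
  perms <- t(vapply(seq_len(epochs), function(e) sample.int(n_frames) - 1L,
                    integer(n_frames)))

  res <- cpp_train_run(data, model$W, model$b, perms, lrs, fps,
                       inr_cfg$omega0, inr_cfg$skip_every,
                       loss_cfg$ssim_window, loss_cfg$ssim_k1^2, loss_cfg$ssim_k2^2,
                       loss_cfg$w_image, loss_cfg$w_seg, loss_cfg$eps,
                       train_cfg$grokfast_alpha, train_cfg$grokfast_lambda)
  model$W <- res$W
  model$b <- lapply(res$b, as.vector)
  log <- data.frame(epoch = seq_len(epochs) - 1L, lr = lrs,
                    loss_image = res$log[, 1], loss_seg = res$log[, 2],
                    total = loss_cfg$w_image * res$log[, 1] +
                      loss_cfg$w_seg * res$log[, 2])
  if (verbose)
    message(sprintf("trained %d epochs: L_image %.4f -> %.4f, L_seg %.4f -> %.4f",
                    epochs, log$loss_image[1], log$loss_image[epochs],
                    log$loss_seg[1], log$loss_seg[epochs]))
  structure(list(model = model, log = log), class = "inr_fit")
}

#' Mean SSIM of a model's reconstruction of its training frames
#'
#' @param model An [inr_model].
#' @param frames The [frame_set()] the model was trained on.
#' @param cfg A [loss_config()] (for the SSIM window).
#' @return Mean per-frame SSIM between the clamped intensity output and the
#'   training frames.
#' @export
training_ssim <- function(model, frames, cfg = loss_config()) {
  geom <- frames$geom
  px <- frame_pixel_grid(geom)
  vals <- vapply(seq_along(frames$angles_deg), function(i) {
    xyz <- frame_to_world(geom, frames$angles_deg[i], px$rows, px$cols)
    out <- inr_evaluate(model, xyz)
    pred <- matrix(pmin(pmax(out[, 1], 0), 1), geom$rows, geom$cols)
    ssim(pred, frames$intensity[[i]], cfg)
  }, numeric(1))
  mean(vals)
}
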