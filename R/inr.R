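#' Coordinate-network architecture configuration
#'
#' The volume function `F(x, y, z) -> (I, S)` is a SIREN multilayer
#' perceptron over harmonically positional-encoded coordinates: `n_layers`
#' linear layers of width `width` with sine activations (frequency scale
#' `omega0` as in the SIREN initialization), additive skip connections every
#' `skip_every` hidden layers, and a 2-unit linear output head: raw B-mode
#' intensity and the segmentation logit.
#'
#' The network input dimension is `3 * (1 + 2 * pe_bands)`: each coordinate
#' contributes its raw value plus `pe_bands` sine/cosine pairs at
#' frequencies `2^j`, `j = 0 .. pe_bands - 1`. With the default 15 bands the
#' input has 93 features.
#'
#' @param pe_bands Number of sine/cosine frequency pairs per coordinate.
#' @param n_layers Total number of linear layers (including the output).
#' @param width Hidden layer width.
#' @param skip_every Additive skip connection period between hidden layers.
#' @param omega0 First-layer frequency scale of the SIREN activations.
#' @return An object of class `inr_config`.
#' @export
inr_config <- function(pe_bands = 15, n_layers = 10, width = 256,
                       skip_every = 2, omega0 = 30) {
  stopifnot(pe_bands >= 0, n_layers >= 2, width >= 1, skip_every >= 0,
            omega0 > 0)
  structure(list(pe_bands = as.integer(pe_bands),
                 n_layers = as.integer(n_layers),
                 width = as.integer(width),
                 skip_every = as.integer(skip_every),
                 omega0 = omega0,
                 input_dim = 3L * (1L + 2L * as.integer(pe_bands)),
                 out_dim = 2L),
            class = "inr_config")
}

#' Harmonic positional encoding of normalized coordinates
#'
#' Per coordinate `x_i` emits
#' `(x_i, sin(k_0 x_i), cos(k_0 x_i), ..., sin(k_{n-1} x_i), cos(k_{n-1} x_i))`
#' with `k_j = 2^j`, concatenated over the three coordinates.
#'
#' @param coords `n x 3` matrix of coordinates (typically in `[-1, 1]`).
#' @param pe_bands Number of frequency pairs; 0 returns the raw coordinates.
#' @return `n x 3*(1+2*pe_bands)` feature matrix.
#' @export
positional_encode <- function(coords, pe_bands) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, pe_bands >= 0)
  per <- 1 + 2 * pe_bands
  out <- matrix(0, nrow(coords), 3 * per)
  for (c in 1:3) {
    x <- coords[, c]
    base <- (c - 1) * per
    out[, base + 1] <- x
    if (pe_bands > 0) {
      for (j in seq_len(pe_bands)) {
        k <- 2^(j - 1)
        out[, base + 2 * j]     <- sin(k * x)
        out[, base + 2 * j + 1] <- cos(k * x)
      }
    }
  }
  out
}

# layer dimensions: input_dim -> width x (n_layers - 1) -> 2
layer_dims <- function(config) {
  c(config$input_dim, rep(config$width, config$n_layers - 1), config$out_dim)
}

#' Initialize an INR model
#'
#' Weights follow the SIREN scheme: the first layer is uniform in
#' `[-1/fan_in, 1/fan_in]`, subsequent layers uniform in
#' `[-sqrt(6/fan_in)/omega0, sqrt(6/fan_in)/omega0]`, so that the scaled
#' pre-activations `omega0 * z` have approximately unit variance. Biases
#' start at zero.
#'
#' @param config An [inr_config()].
#' @param coord_scale Coordinate normalization, from [coord_scale()] (stored
#'   with the model and in its checkpoint).
#' @param seed Integer seed; initialization is deterministic given the seed.
#' @return An object of class `inr_model`.
#' @export
inr_init <- function(config = inr_config(), coord_scale, seed = NULL) {
  stopifnot(inherits(config, "inr_config"))
  if (!is.null(seed)) local_seed(seed)
  dims <- layer_dims(config)
  L <- length(dims) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- dims[l]
    a <- if (l == 1) 1 / fan_in else sqrt(6 / fan_in) / config$omega0
    W[[l]] <- matrix(runif(fan_in * dims[l + 1], -a, a), fan_in, dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  structure(list(config = config, W = W, b = b, coord_scale = coord_scale),
            class = "inr_model")
}

#' @export
print.inr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<inr_model> %d layers, width %d, %d input features (%d PE bands), %s parameters\n",
    cfg$n_layers, cfg$width, cfg$input_dim, cfg$pe_bands,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of an INR model
#' @param model An [inr_model] object (or an [inr_config()]).
#' @export
n_params <- function(model) {
  config <- if (inherits(model, "inr_config")) model else model$config
  dims <- layer_dims(config)
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

#' Evaluate the volume function at arbitrary positions
#'
#' Pure function of the coordinates: the same batch always returns the same
#' values, evaluation is tiled internally so memory stays bounded, and cost
#' per point does not depend on the size of the training data.
#'
#' @param model A trained (or initialized) `inr_model`.
#' @param coords `n x 3` matrix of positions; world mm by default.
#' @param normalized Set `TRUE` if `coords` are already in `[-1, 1]^3`.
#' @param chunk Number of positions per evaluation tile.
#' @return `n x 2` matrix with columns `intensity` (raw, unclamped) and
#'   `mask_prob` (sigmoid output in `[0, 1]`).
#' @export
inr_evaluate <- function(model, coords, normalized = FALSE, chunk = 262144L) {
  stopifnot(inherits(model, "inr_model"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!normalized) coords <- normalize_coords(coords, model$coord_scale)
  cfg <- model$config
  n <- nrow(coords)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("intensity", "mask_prob")))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- cpp_inr_forward(model$W, model$b, coords[i:j, , drop = FALSE],
                                  cfg$pe_bands, cfg$omega0, cfg$skip_every)
    i <- j + 1L
  }
  out
}

#' Save / load an INR checkpoint
#'
#' A checkpoint is a little-endian binary blob of all parameters (doubles,
#' layer by layer, weights then bias) plus a JSON sidecar (`<path>.json`)
#' with the architecture and coordinate scale. Loading validates that the
#' blob length matches the configuration and restores bit-identical weights.
#'
#' @param model An `inr_model`.
#' @param path Checkpoint path (the sidecar is written next to it).
#' @return `save_checkpoint` returns `path` invisibly with the file size in
#'   bytes as attribute `bytes`; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "inr_model"))
  params <- unlist(lapply(seq_along(model$W),
                          function(l) c(model$W[[l]], model$b[[l]])))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(params, con, size = 8, endian = "little")
  meta <- list(format = "usinr-checkpoint-1",
               config = unclass(model$config),
               coord_scale = model$coord_scale,
               n_params = length(params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  res <- path
  attr(res, "bytes") <- length(params) * 8
  invisible(res)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "usinr-checkpoint-1"))
    stop("not a recognized checkpoint sidecar")
  cfg <- inr_config(pe_bands = meta$config$pe_bands,
                    n_layers = meta$config$n_layers,
                    width = meta$config$width,
                    skip_every = meta$config$skip_every,
                    omega0 = meta$config$omega0)
  expect_n <- n_params(cfg)
  if (!is.null(meta$n_params) && meta$n_params != expect_n)
    stop(sprintf("checkpoint shape mismatch: sidecar says %d parameters, config implies %d",
                 meta$n_params, expect_n))
  sz <- file.info(path)$size
  if (is.na(sz) || sz != expect_n * 8)
    stop(sprintf("checkpoint shape mismatch: %d bytes on disk, config implies %d",
                 sz, expect_n * 8))
  con <- file(path, "rb")
  on.exit(close(con))
  params <- readBin(con, "double", n = expect_n, size = 8, endian = "little")
  dims <- layer_dims(cfg)
  L <- length(dims) - 1
  W <- vector("list", L); b <- vector("list", L)
  off <- 0L
  for (l in seq_len(L)) {
    nw <- dims[l] * dims[l + 1]
    W[[l]] <- matrix(params[off + seq_len(nw)], dims[l], dims[l + 1])
    off <- off + nw
    b[[l]] <- params[off + seq_len(dims[l + 1])]
    off <- off + dims[l + 1]
  }
  structure(list(config = cfg, W = W, b = b,
                 coord_scale = meta$coord_scale),
            class = "inr_model")
}
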