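# Shared fixtures. Heavy ones (trained models) are built once per test run
# and memoized; sizes are chosen so the whole suite stays within a desktop
# coffee break.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small geometry used across unit tests
tiny_geom <- function(rows = 32, cols = 32, step = 15) {
  scan_geometry(180, step, axial_extent_mm = 40, lateral_extent_mm = 40,
                rows = rows, cols = cols)
}

# a quickly trained model on a smooth 2-sphere scene (noise-free)
tiny_fit <- function() fixture("tiny_fit", function() {
  geom <- tiny_geom()
  ph <- make_phantom(seed = 5, n_spheres = 2, radius_range_mm = c(6, 10),
                     geom = geom, anechoic = TRUE, speckle_scale = 0)
  frames <- render_sweep(ph, geom, seed = 6)
  fit <- fit_inr(frames,
                 inr_config(pe_bands = 4, n_layers = 4, width = 16),
                 loss_config(),
                 train_config(epochs = 60, lr_init = 3e-4, seed = 7))
  list(fit = fit, frames = frames, phantom = ph, geom = geom)
})

# reduced-scale volumetric study: anechoic 6-sphere phantom, 5-degree sweep,
# noise-free 128^2 frames -- the volume-accuracy experiment at one seed
acc_volume_fit <- function() fixture("acc_volume_fit", function() {
  geom <- scan_geometry(180, 5, rows = 128, cols = 128)
  ph <- make_phantom(seed = 11, n_spheres = 6, anechoic = TRUE, geom = geom,
                     speckle_scale = 0)
  frames <- render_sweep(ph, geom, seed = 12)
  fit <- fit_inr(frames,
                 inr_config(pe_bands = 10, n_layers = 6, width = 48),
                 loss_config(),
                 train_config(epochs = 150, lr_init = 3e-4, seed = 13,
                              frames_per_step = 9))
  vol <- sample_volume(fit$model, grid_for_geometry(geom, 1))
  metrics <- volume_metrics(vol, ph)
  list(fit = fit, frames = frames, phantom = ph, geom = geom,
       volume = vol, metrics = metrics)
})

# angle-resolution study on a smaller phantom: coarse (10 deg) vs fine
# (1.25 deg) sweeps of the same scene at 64^2
acc_angle_study <- function() fixture("acc_angle_study", function() {
  geom <- scan_geometry(180, 5, rows = 64, cols = 64)
  ph <- make_phantom(seed = 41, n_spheres = 4, radius_range_mm = c(6, 14),
                     anechoic = TRUE, geom = geom, speckle_scale = 0)
  angle_resolution_study(ph, geom, steps_deg = c(10, 1.25),
                         inr_cfg = inr_config(pe_bands = 10, n_layers = 6,
                                              width = 48),
                         train_cfg = train_config(epochs = 120, lr_init = 3e-4,
                                                  seed = 42),
                         grid_spacing_mm = 1, seed = 43)
})

# contrast-fidelity run: frozen mild speckle, 2.5-degree sweep at 96^2
acc_contrast_fit <- function() fixture("acc_contrast_fit", function() {
  geom <- scan_geometry(180, 2.5, rows = 96, cols = 96)
  ph <- make_phantom(seed = 11, n_spheres = 6, geom = geom,
                     speckle_scale = 0.3, speckle_grain_mm = 8)
  frames <- render_sweep(ph, geom, seed = 12)
  fit <- fit_inr(frames,
                 inr_config(pe_bands = 10, n_layers = 6, width = 64),
                 loss_config(),
                 train_config(epochs = 150, lr_init = 3e-4, seed = 13))
  list(fit = fit, frames = frames, phantom = ph, geom = geom,
       fidelity = contrast_fidelity(fit$model, frames, ph))
})

# naive sliding-window SSIM, the independent oracle
naive_ssim <- function(x, y, w = 11, k1 = 0.01, k2 = 0.03) {
  C1 <- k1^2; C2 <- k2^2
  R <- nrow(x); C <- ncol(x)
  vals <- numeric(0)
  for (i in 1:(R - w + 1)) for (j in 1:(C - w + 1)) {
    xv <- x[i:(i + w - 1), j:(j + w - 1)]
    yv <- y[i:(i + w - 1), j:(j + w - 1)]
    mx <- mean(xv); my <- mean(yv)
    sx <- mean(xv^2) - mx^2; sy <- mean(yv^2) - my^2
    sxy <- mean(xv * yv) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                ((mx^2 + my^2 + C1) * (sx + sy + C2)))
  }
  mean(vals)
}

# brute-force nearest neighbour with lowest-index tie-break
brute_nn <- function(points, queries) {
  vapply(seq_len(nrow(queries)), function(j) {
    d2 <- (points[, 1] - queries[j, 1])^2 + (points[, 2] - queries[j, 2])^2 +
      (points[, 3] - queries[j, 3])^2
    which.min(d2)  # which.min takes the first minimum: lowest index
  }, integer(1))
}

# raster-order flood fill, the connected-components oracle
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    if (!mask[i1, i2, i3] || lab[i1, i2, i3]) next
    nxt <- nxt + 1L
    stack <- list(c(i1, i2, i3))
    lab[i1, i2, i3] <- nxt
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        n <- v + as.integer(offs[o, ])
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] && !lab[n[1], n[2], n[3]]) {
          lab[n[1], n[2], n[3]] <- nxt
          stack[[length(stack) + 1]] <- n
        }
      }
    }
  }
  lab
}

# visiting order differs from the C++ BFS, but first-voxel raster order of
# components is shared, so label arrays must match exactly
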