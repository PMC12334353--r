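#' Label connected components of a binary 3D mask
#'
#' Maximal connected components under 6-, 18- or 26-connectivity, labelled
#' in deterministic raster order of each component's first voxel.
#'
#' @param mask Binary 3D array.
#' @param connectivity One of 6, 18, 26.
#' @return Integer 3D array of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26), length(dim(mask)) == 3)
  lab <- cpp_label3d(as.integer(mask != 0), as.integer(dim(mask)),
                     as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = dim(mask))
  attr(lab, "n_components") <- n
  lab
}

#' Convex hull mesh and volume of a point set
#'
#' Convex hull of (typically voxel-center) points in mm; the enclosed
#' volume is computed with the divergence theorem over the watertight,
#' outward-oriented triangular mesh. Degenerate inputs (fewer than 4
#' points, collinear or coplanar sets) yield volume 0, no mesh, and a
#' degeneracy flag.
#'
#' @param points_mm `n x 3` matrix of points in mm.
#' @return List of class `hull_mesh`: `vertices` (the input points),
#'   `faces` (`m x 3`, 1-based, outward orientation), `volume_mm3`,
#'   `degenerate`.
#' @export
hull_mesh <- function(points_mm) {
  points_mm <- as.matrix(points_mm)
  res <- cpp_convex_hull(points_mm)
  structure(list(vertices = points_mm, faces = res$faces,
                 volume_mm3 = res$volume, degenerate = res$degenerate),
            class = "hull_mesh")
}

# voxels of a component that touch its boundary (any missing 6-neighbour);
# enough to determine the convex hull while keeping the point set small
surface_voxels <- function(idx3, shape) {
  occ <- array(FALSE, dim = shape)
  occ[idx3] <- TRUE
  full <- rep(TRUE, nrow(idx3))
  for (k in 1:3) {
    for (d in c(-1L, 1L)) {
      nb <- idx3
      nb[, k] <- nb[, k] + d
      inb <- nb[, k] >= 1 & nb[, k] <= shape[k]
      has <- rep(FALSE, nrow(idx3))
      has[inb] <- occ[nb[inb, , drop = FALSE]]
      full <- full & has
    }
  }
  idx3[!full, , drop = FALSE]
}

#' Labelled objects of a mask volume with hull volumetry
#'
#' Labels the connected components of a sampled mask volume and computes,
#' per object, the voxel count, the voxel-count volume, and the volume of
#' the convex hull of its voxel centers.
#'
#' @param volume A `voxel_volume` from [sample_volume()] or a binary 3D
#'   array.
#' @param grid The [grid_spec()] of the volume (taken from a
#'   `voxel_volume` automatically).
#' @param connectivity Component connectivity.
#' @param min_voxels Components smaller than this are dropped (speckle
#'   islands).
#' @return List of class `labeled_objects`: `labels` array, `objects` data
#'   frame (label, voxel_count, voxel_volume_cm3, hull_volume_cm3,
#'   degenerate), `meshes` (list of [hull_mesh()]).
#' @export
labeled_objects <- function(volume, grid = NULL, connectivity = 26,
                            min_voxels = 2) {
  if (inherits(volume, "voxel_volume")) {
    grid <- volume$grid
    mask <- volume$mask
  } else mask <- volume
  if (is.null(grid)) stop("grid must be supplied for a bare mask array")
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n_components")
  voxel_mm3 <- prod(grid$spacing_mm)
  objects <- list(); meshes <- list()
  keep <- 0L
  for (k in seq_len(n)) {
    idx3 <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx3) < min_voxels) { lab[lab == k] <- 0L; next }
    keep <- keep + 1L
    surf <- surface_voxels(idx3, dim(lab))
    pts <- sweep(sweep(surf - 1, 2, grid$spacing_mm, "*"), 2, grid$origin_mm, "+")
    mesh <- hull_mesh(pts)
    objects[[keep]] <- data.frame(
      label = keep, voxel_count = nrow(idx3),
      voxel_volume_cm3 = nrow(idx3) * voxel_mm3 / 1000,
      hull_volume_cm3 = mesh$volume_mm3 / 1000,
      degenerate = mesh$degenerate)
    lab[lab == k] <- keep  # compact labels after dropping small islands
    meshes[[keep]] <- mesh
  }
  structure(list(labels = lab,
                 objects = if (keep) do.call(rbind, objects) else
                   data.frame(label = integer(), voxel_count = integer(),
                              voxel_volume_cm3 = numeric(),
                              hull_volume_cm3 = numeric(),
                              degenerate = logical()),
                 meshes = meshes),
            class = "labeled_objects")
}

#' Dice coefficient and intersection-over-union of binary masks
#'
#' `Dice = 2 |y & yhat| / (sum y + sum yhat)`, `IoU = |y & yhat| / |y | yhat|`;
#' both are 1 for equal non-empty masks and, by convention, 1 when both
#' masks are empty. For binary masks `IoU = Dice / (2 - Dice)`.
#'
#' @param y,yhat Binary arrays of identical size.
#' @export
dice <- function(y, yhat) {
  y <- as.logical(y); yhat <- as.logical(yhat)
  stopifnot(length(y) == length(yhat))
  s <- sum(y) + sum(yhat)
  if (s == 0) return(1)
  2 * sum(y & yhat) / s
}

#' @rdname dice
#' @export
iou <- function(y, yhat) {
  y <- as.logical(y); yhat <- as.logical(yhat)
  stopifnot(length(y) == length(yhat))
  u <- sum(y | yhat)
  if (u == 0) return(1)
  sum(y & yhat) / u
}

#' Relative volume error in percent
#'
#' `100 |V - Vhat| / V`.
#'
#' @param v_true True volume (> 0).
#' @param v_est Estimated volume.
#' @export
volume_error <- function(v_true, v_est) {
  stopifnot(all(v_true > 0))
  100 * abs(v_true - v_est) / v_true
}

#' Contrast between a target region and background, in dB
#'
#' Difference of the mean dB intensity of the two regions,
#' `mu_target - mu_background`; invariant to a constant dB shift of the
#' image.
#'
#' @param db_image Image on the dB scale.
#' @param target_region,background_region Non-empty logical masks (or index
#'   vectors) into `db_image`.
#' @export
contrast_db <- function(db_image, target_region, background_region) {
  t_idx <- if (is.logical(target_region)) which(target_region) else target_region
  b_idx <- if (is.logical(background_region)) which(background_region) else background_region
  if (length(t_idx) == 0 || length(b_idx) == 0) stop("empty region")
  mean(db_image[t_idx]) - mean(db_image[b_idx])
}

# match predicted components to ground-truth labels by maximal overlap
match_components <- function(truth, pred_lab) {
  n_true <- max(truth)
  sapply(seq_len(n_true), function(k) {
    ov <- pred_lab[truth == k]
    ov <- ov[ov > 0]
    if (length(ov) == 0) return(0L)
    as.integer(names(which.max(table(ov))))
  })
}

#' Per-sphere reconstruction metrics of a sampled volume
#'
#' Scores an INR-sampled mask volume against the rasterized ground truth:
#' each true sphere is matched to the predicted connected component with
#' maximal overlap, then Dice, IoU and the voxel-count error (in percent)
#' are computed per sphere.
#'
#' @param volume A `voxel_volume` from [sample_volume()].
#' @param phantom The ground-truth [make_phantom()] scene.
#' @param connectivity Component connectivity.
#' @return Data frame: sphere, radius_mm, true/predicted voxel counts,
#'   dice, iou, voxel_error_pct, volume_cm3 (voxel-count based),
#'   hull_volume_cm3.
#' @export
volume_metrics <- function(volume, phantom, connectivity = 26) {
  gt <- rasterize_ground_truth(phantom, volume$grid)
  obj <- labeled_objects(volume, connectivity = connectivity)
  matched <- match_components(gt$labels, obj$labels)
  voxel_mm3 <- prod(volume$grid$spacing_mm)
  n <- nrow(phantom$spheres)
  out <- lapply(seq_len(n), function(k) {
    true_k <- gt$labels == k
    m <- matched[k]
    pred_k <- if (m > 0) obj$labels == m else array(FALSE, dim = dim(gt$labels))
    n_pred <- sum(pred_k)
    data.frame(sphere = k,
               radius_mm = phantom$spheres$radius_mm[k],
               true_voxels = sum(true_k), pred_voxels = n_pred,
               dice = dice(true_k, pred_k), iou = iou(true_k, pred_k),
               voxel_error_pct = volume_error(sum(true_k), n_pred),
               volume_cm3 = n_pred * voxel_mm3 / 1000,
               hull_volume_cm3 = if (m > 0)
                 obj$objects$hull_volume_cm3[obj$objects$label == m] else 0)
  })
  do.call(rbind, out)
}

#' Effect of the rotation-angle resolution on volume accuracy
#'
#' For each angular step, renders the sweep, trains an INR, samples the
#' volume, labels it and scores every sphere against the rasterized ground
#' truth. Reproduces the angle-resolution experiment at a configurable
#' scale.
#'
#' @param phantom A [make_phantom()] scene.
#' @param geom A [scan_geometry()] template (its `step_deg` is replaced).
#' @param steps_deg Angular steps to evaluate.
#' @param inr_cfg,loss_cfg,train_cfg Pipeline configuration.
#' @param grid_spacing_mm Sampling grid spacing for volumetry.
#' @param threshold Mask probability threshold.
#' @param seed Seed for speckle rendering (training seeds come from
#'   `train_cfg`).
#' @param keep_fits Also return the trained models and frame sets.
#' @return List of class `angle_study`: `table` (per step and sphere, plus
#'   `mean` rows with sphere = NA), and optionally `fits`.
#' @export
angle_resolution_study <- function(phantom, geom, steps_deg,
                                   inr_cfg = inr_config(), loss_cfg = loss_config(),
                                   train_cfg = train_config(),
                                   grid_spacing_mm = 1, threshold = 0.5,
                                   seed = 1, keep_fits = FALSE) {
  rows <- list(); fits <- list()
  grid <- grid_for_geometry(geom, grid_spacing_mm)
  for (st in steps_deg) {
    g <- scan_geometry(geom$sweep_deg, st, geom$axial_extent_mm,
                       geom$lateral_extent_mm, geom$rows, geom$cols,
                       geom$axis_col)
    frames <- render_sweep(phantom, g, seed = seed)
    fit <- fit_inr(frames, inr_cfg, loss_cfg, train_cfg)
    vol <- sample_volume(fit$model, grid, threshold)
    met <- volume_metrics(vol, phantom)
    met$step_deg <- st
    mean_row <- met[1, ]
    mean_row$sphere <- NA
    mean_row[c("radius_mm", "true_voxels", "pred_voxels")] <- NA
    mean_row$dice <- mean(met$dice); mean_row$iou <- mean(met$iou)
    mean_row$voxel_error_pct <- mean(met$voxel_error_pct)
    mean_row$volume_cm3 <- NA; mean_row$hull_volume_cm3 <- NA
    rows[[length(rows) + 1]] <- rbind(met, mean_row)
    if (keep_fits) fits[[as.character(st)]] <- list(fit = fit, frames = frames)
  }
  structure(list(table = do.call(rbind, rows),
                 fits = if (keep_fits) fits else NULL),
            class = "angle_study")
}

#' Contrast fidelity of an INR reconstruction
#'
#' For every frame and every sphere visible in it, computes the contrast
#' (target region mean minus background mean, on the dB-scale image) of
#' the original frame and of the INR-resampled frame, using the exact
#' geometric regions. Reports the per-pair absolute deviation and its mean.
#'
#' @param model A trained [inr_model].
#' @param frames The training [frame_set()].
#' @param phantom The [make_phantom()] scene (for the regions).
#' @param min_region_px Minimum target disc size for a (frame, sphere) pair
#'   to enter the average; tiny grazing slices carry no reliable region
#'   mean.
#' @param db_floor Amplitude floor before the log (guards zeros).
#' @return List: `mean_abs_dev_db` and the per-pair `table`.
#' @export
contrast_fidelity <- function(model, frames, phantom, min_region_px = 30,
                              db_floor = 1e-4) {
  geom <- frames$geom
  px <- frame_pixel_grid(geom)
  to_db <- function(v) 20 * log10(pmax(v, db_floor))
  rows <- list()
  for (i in seq_along(frames$angles_deg)) {
    xyz <- frame_to_world(geom, frames$angles_deg[i], px$rows, px$cols)
    hit <- point_sphere(phantom, xyz)
    bg <- hit == 0L
    present <- setdiff(unique(hit), 0L)
    if (length(present) == 0) next
    orig_db <- to_db(as.vector(frames$intensity[[i]]))
    pred <- inr_evaluate(model, xyz)[, 1]
    pred_db <- to_db(pmin(pmax(pred, 0), 1))
    for (k in present) {
      reg <- hit == k
      if (sum(reg) < min_region_px) next
      c_orig <- mean(orig_db[reg]) - mean(orig_db[bg])
      c_inr <- mean(pred_db[reg]) - mean(pred_db[bg])
      rows[[length(rows) + 1]] <- data.frame(
        frame = i, angle_deg = frames$angles_deg[i], sphere = k,
        region_px = sum(reg), contrast_orig_db = c_orig,
        contrast_inr_db = c_inr, abs_dev_db = abs(c_orig - c_inr))
    }
  }
  tab <- do.call(rbind, rows)
  list(mean_abs_dev_db = if (is.null(tab)) NA_real_ else mean(tab$abs_dev_db),
       table = tab)
}
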