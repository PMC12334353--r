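#' Axis-aligned voxel grid specification
#'
#' Voxel centers sit at `origin + index * spacing` (0-based indices), world
#' mm coordinates.
#'
#' @param origin_mm 3-vector, center of voxel (0, 0, 0).
#' @param spacing_mm 3-vector of positive voxel spacings.
#' @param shape 3 positive integers.
#' @export
grid_spec <- function(origin_mm, spacing_mm, shape) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  shape <- rep_len(as.integer(shape), 3)
  stopifnot(all(spacing_mm > 0), all(shape >= 1), length(origin_mm) == 3)
  structure(list(origin_mm = as.numeric(origin_mm), spacing_mm = spacing_mm,
                 shape = shape),
            class = "grid_spec")
}

#' Grid covering the cylinder swept by a rotational acquisition
#'
#' @param geom A [scan_geometry()].
#' @param spacing_mm Isotropic (or per-axis) voxel spacing.
#' @export
grid_for_geometry <- function(geom, spacing_mm = 1) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  half <- geom$lateral_extent_mm / 2
  ext <- c(geom$axial_extent_mm, geom$lateral_extent_mm, geom$lateral_extent_mm)
  grid_spec(origin_mm = c(0, -half, -half), spacing_mm = spacing_mm,
            shape = floor(ext / spacing_mm) + 1L)
}

#' Voxel-center world coordinates of a grid, column-major order
#' @param grid A [grid_spec()].
#' @return `prod(shape) x 3` matrix (first axis varies fastest).
#' @export
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin_mm[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing_mm[k])
  n1 <- grid$shape[1]; n2 <- grid$shape[2]; n3 <- grid$shape[3]
  cbind(x = rep(ax[[1]], times = n2 * n3),
        y = rep(rep(ax[[2]], each = n1), times = n3),
        z = rep(ax[[3]], each = n1 * n2))
}

#' Sample a trained INR on a voxel grid
#'
#' Evaluates every voxel center (tiled to bound memory), clamps the
#' intensity head to `[0, 1]` and thresholds the mask probability.
#'
#' @param model An [inr_model].
#' @param grid A [grid_spec()].
#' @param threshold Mask probability threshold in (0, 1).
#' @param chunk Evaluation tile size.
#' @return A `voxel_volume`: list with `grid`, `intensity` (3D array in
#'   `[0, 1]`) and `mask` (3D 0/1 integer array).
#' @export
sample_volume <- function(model, grid, threshold = 0.5, chunk = 262144L) {
  stopifnot(threshold > 0, threshold < 1)
  out <- inr_evaluate(model, grid_coords(grid), chunk = chunk)
  structure(list(grid = grid,
                 intensity = array(pmin(pmax(out[, 1], 0), 1), dim = grid$shape),
                 mask = array(as.integer(out[, 2] >= threshold), dim = grid$shape)),
            class = "voxel_volume")
}

#' Resample the volume on an arbitrary plane
#'
#' Builds the coordinate grid of an axis-aligned plane at any offset and
#' in-plane resolution -- including planes and resolutions never present in
#' the acquisition -- and evaluates the INR there.
#'
#' @param model An [inr_model].
#' @param axis `"x"` (plane of constant depth), `"y"` or `"z"`.
#' @param offset_mm Plane position along `axis`.
#' @param res In-plane resolution (side length in pixels).
#' @param threshold Mask probability threshold.
#' @return List with `intensity` and `mask` `res x res` matrices plus the
#'   in-plane axis ranges.
#' @export
reslice <- function(model, axis = c("x", "y", "z"), offset_mm, res = 256,
                    threshold = 0.5) {
  axis <- match.arg(axis)
  sc <- model$coord_scale
  half <- sc$lateral_extent_mm / 2
  ax_range <- function(a) if (a == "x") c(0, sc$axial_extent_mm) else c(-half, half)
  axes <- setdiff(c("x", "y", "z"), axis)
  r1 <- ax_range(axes[1]); r2 <- ax_range(axes[2])
  u <- if (res == 1) mean(r1) else seq(r1[1], r1[2], length.out = res)
  v <- if (res == 1) mean(r2) else seq(r2[1], r2[2], length.out = res)
  pts <- matrix(0, res * res, 3, dimnames = list(NULL, c("x", "y", "z")))
  pts[, axis] <- offset_mm
  pts[, axes[1]] <- rep(u, times = res)
  pts[, axes[2]] <- rep(v, each = res)
  out <- inr_evaluate(model, pts)
  list(intensity = matrix(pmin(pmax(out[, 1], 0), 1), res, res),
       mask = matrix(as.integer(out[, 2] >= threshold), res, res),
       axes = axes, ranges = list(r1, r2))
}

#' Resample the volume on an oblique plane
#'
#' @param model An [inr_model].
#' @param origin_mm Plane center.
#' @param e1,e2 Orthonormal in-plane direction vectors (mm frame).
#' @param extent_mm In-plane physical side lengths (length-2).
#' @param res In-plane resolution.
#' @param threshold Mask probability threshold.
#' @export
reslice_oblique <- function(model, origin_mm, e1, e2, extent_mm, res = 256,
                            threshold = 0.5) {
  u <- seq(-extent_mm[1] / 2, extent_mm[1] / 2, length.out = res)
  v <- seq(-extent_mm[2] / 2, extent_mm[2] / 2, length.out = res)
  pts <- outer(rep(1, res * res), origin_mm) +
    rep(u, times = res) %o% e1 + rep(v, each = res) %o% e2
  out <- inr_evaluate(model, pts)
  list(intensity = matrix(pmin(pmax(out[, 1], 0), 1), res, res),
       mask = matrix(as.integer(out[, 2] >= threshold), res, res))
}

#' Exact nearest-neighbour interpolation of scattered data
#'
#' Every query receives the value of its Euclidean-nearest datum (exact k-d
#' tree search, no approximation); ties are broken toward the lowest datum
#' index so results are deterministic.
#'
#' @param points `n x 3` matrix of datum positions.
#' @param values Length-`n` vector or `n x k` matrix of datum values.
#' @param queries `m x 3` matrix of query positions.
#' @return Interpolated values (vector or matrix matching `values`).
#' @export
nn_interpolate <- function(points, values, queries) {
  points <- as.matrix(points); queries <- as.matrix(queries)
  if (nrow(points) < 1) stop("need at least one data point")
  stopifnot(ncol(points) == 3, ncol(queries) == 3)
  idx <- cpp_nn_query(points, queries)
  if (is.matrix(values)) values[idx, , drop = FALSE] else values[idx]
}

#' Scattered training data of a frame set
#'
#' World coordinates and values of every pixel of every frame, the input of
#' the nearest-neighbour baseline.
#'
#' @param frames A [frame_set()].
#' @return List with `points` (`n x 3`), `intensity` and `mask` vectors.
#' @export
frameset_points <- function(frames) {
  geom <- frames$geom
  px <- frame_pixel_grid(geom)
  pts <- do.call(rbind, lapply(frames$angles_deg, function(a)
    frame_to_world(geom, a, px$rows, px$cols)))
  list(points = pts,
       intensity = unlist(lapply(frames$intensity, as.vector)),
       mask = unlist(lapply(frames$mask, as.vector)))
}

#' Compare INR and nearest-neighbour reslicing against ground truth
#'
#' For a set of constant-depth planes, reconstructs the segmentation mask
#' with both methods and scores each against the phantom's analytic mask.
#' Wall times are informational only.
#'
#' @param model A trained [inr_model].
#' @param frames The training [frame_set()].
#' @param phantom The ground-truth [make_phantom()] scene.
#' @param offsets_mm Depths of the evaluated planes.
#' @param res In-plane resolution.
#' @param threshold Mask probability threshold.
#' @return Data frame: slice offset, method, dice, iou, wall seconds.
#' @export
compare_methods <- function(model, frames, phantom, offsets_mm, res = 128,
                            threshold = 0.5) {
  sc <- model$coord_scale
  half <- sc$lateral_extent_mm / 2
  data <- frameset_points(frames)
  rows <- list()
  for (off in offsets_mm) {
    u <- seq(-half, half, length.out = res)
    pts <- cbind(x = off, y = rep(u, times = res), z = rep(u, each = res))
    truth <- as.integer(point_sphere(phantom, pts) > 0)

    t0 <- proc.time()[["elapsed"]]
    sl <- reslice(model, "x", off, res, threshold)
    t_inr <- proc.time()[["elapsed"]] - t0
    m_inr <- as.vector(sl$mask)

    t0 <- proc.time()[["elapsed"]]
    m_nn <- as.integer(nn_interpolate(data$points, data$mask, pts) >= 0.5)
    t_nn <- proc.time()[["elapsed"]] - t0

    rows[[length(rows) + 1]] <- data.frame(
      slice_mm = off,
      method = c("inr", "nn"),
      dice = c(dice(truth, m_inr), dice(truth, m_nn)),
      iou = c(iou(truth, m_inr), iou(truth, m_nn)),
      wall_s = c(t_inr, t_nn))
  }
  do.call(rbind, rows)
}
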