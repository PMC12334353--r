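#' Rotational scan geometry
#'
#' Describes a rotational B-mode sweep: a 1D array sweeping an angular range
#' about the depth line through `axis_col`, together with the per-frame image
#' raster. The image plane at angle 0 is the x-y plane; positive x is depth
#' (axial, 0 at the transducer face) and a pixel with signed lateral offset
#' `l` maps to `(x, l*cos(theta), l*sin(theta))`.
#'
#' Pixel centers carry the coordinates: the first and last rows/columns land
#' exactly on the field-of-view bounds, so spacing is `extent / (n - 1)`.
#' Pixel indices are 0-based throughout, matching the on-disk manifest
#' convention.
#'
#' @param sweep_deg Total angular range of the sweep in degrees.
#' @param step_deg Angular increment between frames in degrees. Must divide
#'   `sweep_deg` evenly (tolerance 1e-9).
#' @param axial_extent_mm Depth of the field of view in mm.
#' @param lateral_extent_mm Width of the field of view in mm.
#' @param rows,cols Frame raster size (rows = axial samples, cols = lateral).
#' @param axis_col Fractional 0-based column index of the rotation axis.
#'   Defaults to the lateral center of the pixel raster, `(cols - 1) / 2`,
#'   so that the corner pixels map symmetrically onto the lateral bounds.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(sweep_deg = 180, step_deg = 1.25,
                          axial_extent_mm = 55, lateral_extent_mm = 82,
                          rows = 256, cols = 256,
                          axis_col = (cols - 1) / 2) {
  stopifnot(sweep_deg > 0, step_deg > 0,
            axial_extent_mm > 0, lateral_extent_mm > 0,
            rows >= 2, cols >= 2)
  k <- sweep_deg / step_deg
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("step_deg (%g) does not divide sweep_deg (%g) evenly",
                 step_deg, sweep_deg))
  }
  structure(list(sweep_deg = sweep_deg, step_deg = step_deg,
                 axial_extent_mm = axial_extent_mm,
                 lateral_extent_mm = lateral_extent_mm,
                 rows = as.integer(rows), cols = as.integer(cols),
                 axis_col = axis_col),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %g deg sweep in %g deg steps (%d frames)\n",
              x$sweep_deg, x$step_deg, length(plan_sweep(x$sweep_deg, x$step_deg))))
  cat(sprintf("  field of view: %.1f mm axial x %.1f mm lateral, raster %d x %d\n",
              x$axial_extent_mm, x$lateral_extent_mm, x$rows, x$cols))
  invisible(x)
}

#' Plan the frame angles of a rotational sweep
#'
#' Returns the half-open sequence of acquisition angles
#' `0, step, 2*step, ..., sweep - step`. The closing angle is excluded
#' because for a 180 degree sweep that plane duplicates the 0 degree plane;
#' a 180 degree sweep at 1.25 degree steps therefore yields 144 frames.
#'
#' @param sweep_deg Total angular range (degrees), or a [scan_geometry()].
#' @param step_deg Angular increment (degrees); ignored when `sweep_deg` is a
#'   geometry object.
#' @return Numeric vector of frame angles in degrees.
#' @export
plan_sweep <- function(sweep_deg, step_deg) {
  if (inherits(sweep_deg, "scan_geometry")) {
    g <- sweep_deg
    sweep_deg <- g$sweep_deg
    step_deg <- g$step_deg
  }
  stopifnot(sweep_deg > 0, step_deg > 0)
  k <- sweep_deg / step_deg
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("step_deg (%g) does not divide sweep_deg (%g) evenly",
                 step_deg, sweep_deg))
  }
  step_deg * (seq_len(round(k)) - 1)
}

#' Map frame pixels to 3D world coordinates
#'
#' @param geom A [scan_geometry()].
#' @param angle_deg Rotation angle of the frame in degrees.
#' @param pixel_rows,pixel_cols 0-based pixel indices (paired vectors).
#' @return An `n x 3` matrix with columns `x`, `y`, `z` in mm.
#' @export
frame_to_world <- function(geom, angle_deg, pixel_rows, pixel_cols) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (length(pixel_rows) != length(pixel_cols))
    stop("pixel_rows and pixel_cols must have the same length")
  if (any(pixel_rows < 0 | pixel_rows > geom$rows - 1) ||
      any(pixel_cols < 0 | pixel_cols > geom$cols - 1))
    stop("pixel indices outside the frame raster")
  th <- (angle_deg %% 360) * pi / 180  # exact periodicity: 370 and 10 coincide
  x <- pixel_rows * (geom$axial_extent_mm / (geom$rows - 1))
  l <- (pixel_cols - geom$axis_col) * (geom$lateral_extent_mm / (geom$cols - 1))
  cbind(x = x, y = l * cos(th), z = l * sin(th))
}

#' All pixel centers of a frame, in column-major raster order
#'
#' Convenience companion to [frame_to_world()]: the returned order matches
#' the linearization of an R `rows x cols` matrix, so frame images can be
#' paired with coordinates via `as.vector()`.
#'
#' @param geom A [scan_geometry()].
#' @return List with 0-based `rows` and `cols` index vectors.
#' @export
frame_pixel_grid <- function(geom) {
  list(rows = rep(seq_len(geom$rows) - 1L, times = geom$cols),
       cols = rep(seq_len(geom$cols) - 1L, each = geom$rows))
}

#' Normalize world coordinates to the unit cube
#'
#' Affine map used to condition coordinates for the periodic encoder:
#' `x -> 2 x / axial_extent - 1` and `y, z -> y / (lateral_extent / 2)`.
#' Values outside `[-1, 1]` are permitted (extrapolation).
#'
#' @param coords `n x 3` matrix of world coordinates (mm).
#' @param geom A [scan_geometry()] or a `coord_scale` list with elements
#'   `axial_extent_mm` and `lateral_extent_mm`.
#' @return `n x 3` matrix of normalized coordinates.
#' @export
normalize_coords <- function(coords, geom) {
  coords <- as.matrix(coords)
  cbind(2 * coords[, 1] / geom$axial_extent_mm - 1,
        coords[, 2] / (geom$lateral_extent_mm / 2),
        coords[, 3] / (geom$lateral_extent_mm / 2))
}

#' @rdname normalize_coords
#' @export
denormalize_coords <- function(coords, geom) {
  coords <- as.matrix(coords)
  cbind(x = (coords[, 1] + 1) * geom$axial_extent_mm / 2,
        y = coords[, 2] * geom$lateral_extent_mm / 2,
        z = coords[, 3] * geom$lateral_extent_mm / 2)
}

#' @rdname normalize_coords
#' @export
coord_scale <- function(geom) {
  list(axial_extent_mm = geom$axial_extent_mm,
       lateral_extent_mm = geom$lateral_extent_mm)
}
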