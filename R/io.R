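#' Write a frame set to disk (TIFF frames + JSON manifest)
#'
#' Frames go to one multi-page 16-bit TIFF, masks to one multi-page 8-bit
#' TIFF, and the geometry, angles and provenance to a JSON manifest.
#'
#' @param frames A [frame_set()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the three files.
#' @param provenance Optional list recorded verbatim in the manifest
#'   (seeds, phantom description, ...).
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(frames, dir, name = "dataset", provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames_file <- paste0(name, "_frames.tif")
  masks_file <- paste0(name, "_masks.tif")
  tiff::writeTIFF(frames$intensity, file.path(dir, frames_file),
                  bits.per.sample = 16)
  tiff::writeTIFF(lapply(frames$mask, function(m) m * 1.0),
                  file.path(dir, masks_file), bits.per.sample = 8)
  manifest <- list(
    schema_version = 1,
    geometry = unclass(frames$geom),
    angles_deg = frames$angles_deg,
    frames = frames_file,
    masks = masks_file,
    provenance = provenance)
  path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame set from a JSON manifest
#'
#' Intensities are rescaled to `[0, 1]` from the integer TIFF range and
#' masks binarized at > 0. Validation errors name the offending quantity.
#'
#' @param manifest_path Path to the manifest written by [write_dataset()].
#' @return A [frame_set()].
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  g <- man$geometry
  geom <- scan_geometry(g$sweep_deg, g$step_deg, g$axial_extent_mm,
                        g$lateral_extent_mm, g$rows, g$cols, g$axis_col)
  dir <- dirname(manifest_path)
  for (f in c(man$frames, man$masks)) {
    if (!file.exists(file.path(dir, f)))
      stop("referenced file missing: ", f)
  }
  angles <- as.numeric(man$angles_deg)
  if (is.unsorted(angles, strictly = TRUE))
    stop("angles are not strictly increasing")
  intensity <- tiff::readTIFF(file.path(dir, man$frames), all = TRUE)
  if (!is.list(intensity)) intensity <- list(intensity)
  masks <- tiff::readTIFF(file.path(dir, man$masks), all = TRUE)
  if (!is.list(masks)) masks <- list(masks)
  if (length(angles) != length(intensity))
    stop(sprintf("manifest lists %d angles but %d frames are on disk",
                 length(angles), length(intensity)))
  if (length(masks) != length(intensity))
    stop(sprintf("%d frames but %d masks on disk", length(intensity), length(masks)))
  masks <- lapply(masks, function(m) (m > 0) * 1L)
  frame_set(angles_deg = angles, intensity = intensity, mask = masks, geom = geom)
}

#' Write a sampled volume (or label array) as NIfTI-1
#'
#' @param x A `voxel_volume`, `labeled_objects`, or 3D array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param grid [grid_spec()] supplying voxel spacing when `x` is an array.
#' @param what For a `voxel_volume`: `"intensity"` or `"mask"`.
#' @export
write_volume_nifti <- function(x, path, grid = NULL, what = "intensity") {
  if (inherits(x, "voxel_volume")) { grid <- x$grid; arr <- x[[what]] }
  else if (inherits(x, "labeled_objects")) { arr <- x$labels }
  else arr <- x
  img <- RNifti::asNifti(arr * 1.0)
  if (!is.null(grid)) RNifti::pixdim(img) <- grid$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a triangular mesh as ASCII PLY or STL
#'
#' @param mesh A [hull_mesh()].
#' @param path Output path.
#' @export
write_mesh_ply <- function(mesh, path) {
  if (mesh$degenerate) stop("cannot write a degenerate mesh")
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
write_mesh_stl <- function(mesh, path) {
  if (mesh$degenerate) stop("cannot write a degenerate mesh")
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid usinr", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- c((b[2]-a[2])*(c3[3]-a[3]) - (b[3]-a[3])*(c3[2]-a[2]),
           (b[3]-a[3])*(c3[1]-a[1]) - (b[1]-a[1])*(c3[3]-a[3]),
           (b[1]-a[1])*(c3[2]-a[2]) - (b[2]-a[2])*(c3[1]-a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.6f %.6f %.6f", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.6f %.6f %.6f", c(a[1], b[1], c3[1]),
                         c(a[2], b[2], c3[2]), c(a[3], b[3], c3[3])),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid usinr", con)
  invisible(path)
}
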