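#' Random sphere phantom
#'
#' Generates a ground-truth scene of non-overlapping spheres inside the
#' cylinder swept by the rotating frame: uniformly drawn radii and contrasts,
#' centers placed by rejection sampling so that every sphere lies fully
#' inside the field of view. Contrasts are expressed in dB relative to the
#' background amplitude; `anechoic = TRUE` makes every target echo-free
#' (contrast `-Inf`, i.e. amplitude 0), emulating fluid-filled targets such
#' as follicles or water beads.
#'
#' @param seed Integer seed; the phantom is reproducible given the seed.
#' @param n_spheres Number of spheres.
#' @param radius_range_mm Range the sphere radii are drawn from, in mm.
#'   Set `size_is_diameter = TRUE` to interpret the range as diameters.
#' @param contrast_range_db Range the sphere contrasts are drawn from (dB
#'   over background). Ignored when `anechoic = TRUE`.
#' @param geom A [scan_geometry()] defining the swept cylinder the spheres
#'   must fit into.
#' @param anechoic If `TRUE` all spheres are echo-free.
#' @param background_level Mean background amplitude in (0, 1).
#' @param speckle_scale Strength of the multiplicative unit-mean Rayleigh
#'   speckle, from 0 (noise-free) to 1 (fully developed speckle).
#' @param speckle_mode `"frozen"` (default) evaluates a fixed 3D speckle
#'   field attached to the phantom -- the envelope of a complex Gaussian
#'   random field, emulating the stationary scatterers of a real volume, so
#'   the same world point carries the same speckle in every frame.
#'   `"frame"` draws independent per-pixel noise for every rendered frame
#'   (speckle decorrelated between frames).
#' @param speckle_grain_mm Approximate speckle grain size (correlation
#'   length) of the frozen field, in mm.
#' @param size_is_diameter Interpret `radius_range_mm` as diameters.
#' @param min_gap_mm Minimum surface-to-surface clearance between spheres.
#'   Per-object volumetry presupposes individually resolvable targets, so the
#'   default keeps neighbours at least an azimuthal sampling distance apart
#'   (3 mm, the 5-degree arc length at mid-field radius); set 0 to allow
#'   arbitrarily close non-overlapping spheres.
#' @param max_attempts Rejection-sampling budget for sphere placement.
#' @return An object of class `sphere_phantom` with a `spheres` data frame
#'   (center coordinates, radius, contrast, label).
#' @export
make_phantom <- function(seed = NULL, n_spheres = 6,
                         radius_range_mm = c(4, 15),
                         contrast_range_db = c(-2, 8),
                         geom = scan_geometry(),
                         anechoic = FALSE,
                         background_level = 0.25,
                         speckle_scale = 1,
                         size_is_diameter = FALSE,
                         min_gap_mm = 3,
                         speckle_mode = c("frozen", "frame"),
                         speckle_grain_mm = 2,
                         max_attempts = 10000) {
  speckle_mode <- match.arg(speckle_mode)
  stopifnot(n_spheres >= 1, diff(radius_range_mm) >= 0,
            background_level > 0, background_level < 1,
            speckle_scale >= 0, speckle_scale <= 1)
  if (!is.null(seed)) local_seed(seed)
  r_cyl <- geom$lateral_extent_mm / 2
  depth <- geom$axial_extent_mm
  if (max(radius_range_mm) / (if (size_is_diameter) 2 else 1) > min(r_cyl, depth / 2))
    stop("radius_range_mm does not fit inside the scan geometry")

  radii <- runif(n_spheres, radius_range_mm[1], radius_range_mm[2])
  if (size_is_diameter) radii <- radii / 2
  contrasts <- if (anechoic) rep(-Inf, n_spheres)
               else runif(n_spheres, contrast_range_db[1], contrast_range_db[2])

  centers <- matrix(NA_real_, n_spheres, 3)
  for (i in seq_len(n_spheres)) {
    r <- radii[i]
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      # uniform in the shrunken cylinder that keeps the sphere inside
      x <- runif(1, r, depth - r)
      rho <- (r_cyl - r) * sqrt(runif(1))
      phi <- runif(1, 0, 2 * pi)
      cand <- c(x, rho * cos(phi), rho * sin(phi))
      ok <- TRUE
      if (i > 1) {
        d <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        ok <- all(d > radii[seq_len(i - 1)] + r + min_gap_mm)
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place non-overlapping spheres; use fewer or smaller spheres")
  }
  # frozen speckle: two independent Gaussian random fields (sums of random
  # plane waves); their envelope is Rayleigh with the chosen grain size
  field <- NULL
  if (speckle_mode == "frozen") {
    K <- 96L
    wavelen <- runif(2 * K, speckle_grain_mm, 2 * speckle_grain_mm)
    dirs <- matrix(rnorm(6 * K), 2 * K, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    field <- list(k = dirs * (2 * pi / wavelen), phase = runif(2 * K, 0, 2 * pi),
                  K = K)
  }
  structure(list(
    spheres = data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                         radius_mm = radii, contrast_db = contrasts,
                         label = seq_len(n_spheres)),
    background_level = background_level,
    speckle_scale = speckle_scale,
    speckle_mode = speckle_mode,
    speckle_field = field,
    extents_mm = list(axial = depth, radial = r_cyl)),
    class = "sphere_phantom")
}

# unit-mean Rayleigh envelope of the phantom's frozen speckle field at a set
# of world points
speckle_envelope <- function(phantom, xyz) {
  f <- phantom$speckle_field
  ph <- matrix(xyz %*% t(f$k), nrow = nrow(xyz))
  ph <- cos(sweep(ph, 2, f$phase, "+")) * sqrt(2 / f$K)
  re <- rowSums(ph[, seq_len(f$K), drop = FALSE])
  im <- rowSums(ph[, f$K + seq_len(f$K), drop = FALSE])
  sqrt(re^2 + im^2) / sqrt(pi / 2)
}

#' @export
print.sphere_phantom <- function(x, ...) {
  cat(sprintf("<sphere_phantom> %d spheres, background %.2f, speckle %.2f\n",
              nrow(x$spheres), x$background_level, x$speckle_scale))
  print(x$spheres, digits = 3)
  invisible(x)
}

# amplitude level per sphere: background * 10^(dB/20); anechoic -> 0
sphere_levels <- function(phantom) {
  ifelse(is.finite(phantom$spheres$contrast_db),
         phantom$background_level * 10^(phantom$spheres$contrast_db / 20), 0)
}

# per-sphere membership of a set of world points: integer sphere row or 0
point_sphere <- function(phantom, xyz) {
  hit <- integer(nrow(xyz))
  s <- phantom$spheres
  for (i in seq_len(nrow(s))) {
    d2 <- (xyz[, 1] - s$cx[i])^2 + (xyz[, 2] - s$cy[i])^2 + (xyz[, 3] - s$cz[i])^2
    hit[d2 < s$radius_mm[i]^2] <- i
  }
  hit
}

#' Render one B-mode-like frame of a phantom
#'
#' Geometric renderer standing in for a full acoustic simulation: the
#' noise-free amplitude of a pixel is the background level scaled by
#' `10^(contrast_db/20)` inside a sphere (0 for anechoic spheres), then
#' multiplied by unit-mean Rayleigh speckle blended in with weight
#' `speckle_scale`, and clipped to `[0, 1]`. Masks are rendered noise-free
#' from geometry alone.
#'
#' @param phantom A [make_phantom()] scene.
#' @param geom A [scan_geometry()].
#' @param angle_deg Rotation angle of the frame.
#' @param noise_seed Optional seed for the speckle draw.
#' @return List with `intensity` and `mask` matrices (`rows x cols`).
#' @export
render_frame <- function(phantom, geom, angle_deg, noise_seed = NULL) {
  if (!is.null(noise_seed)) local_seed(noise_seed)
  px <- frame_pixel_grid(geom)
  xyz <- frame_to_world(geom, angle_deg, px$rows, px$cols)
  hit <- point_sphere(phantom, xyz)
  levels <- c(phantom$background_level, sphere_levels(phantom))
  img <- levels[hit + 1L]
  s <- phantom$speckle_scale
  if (s > 0) {
    env <- if (identical(phantom$speckle_mode, "frame") ||
               is.null(phantom$speckle_field)) {
      sqrt(2 / pi) * sqrt(-2 * log(runif(length(img))))  # unit-mean Rayleigh
    } else speckle_envelope(phantom, xyz)
    img <- img * (1 + s * (env - 1))
  }
  img <- pmin(pmax(img, 0), 1)
  list(intensity = matrix(img, geom$rows, geom$cols),
       mask = matrix(as.integer(hit > 0), geom$rows, geom$cols))
}

#' Render a full rotational sweep of a phantom
#'
#' @inheritParams render_frame
#' @param seed Seed for the speckle noise of the whole sweep.
#' @return A [frame_set()].
#' @export
render_sweep <- function(phantom, geom, seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  angles <- plan_sweep(geom)
  frames <- lapply(angles, function(a) render_frame(phantom, geom, a))
  frame_set(angles_deg = angles,
            intensity = lapply(frames, `[[`, "intensity"),
            mask = lapply(frames, `[[`, "mask"),
            geom = geom)
}

#' Ordered set of co-registered frames
#'
#' Container pairing per-frame intensity images in `[0, 1]` and binary masks
#' with their acquisition angles and the shared scan geometry.
#'
#' @param angles_deg Numeric vector of frame angles.
#' @param intensity List of `rows x cols` matrices with values in `[0, 1]`.
#' @param mask List of binary matrices of the same size.
#' @param geom A [scan_geometry()].
#' @export
frame_set <- function(angles_deg, intensity, mask, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  n <- length(angles_deg)
  if (length(intensity) != n || length(mask) != n)
    stop(sprintf("angle count (%d) must equal frame count (%d) and mask count (%d)",
                 n, length(intensity), length(mask)))
  for (i in seq_len(n)) {
    if (!all(dim(intensity[[i]]) == c(geom$rows, geom$cols)))
      stop(sprintf("frame %d does not match the geometry raster", i))
    if (!all(dim(mask[[i]]) == c(geom$rows, geom$cols)))
      stop(sprintf("mask %d does not match the geometry raster", i))
    if (min(intensity[[i]]) < 0 || max(intensity[[i]]) > 1)
      stop(sprintf("frame %d has intensities outside [0, 1]", i))
    if (!all(mask[[i]] %in% c(0, 1)))
      stop(sprintf("mask %d is not binary", i))
  }
  structure(list(angles_deg = angles_deg, intensity = intensity,
                 mask = mask, geom = geom),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames of %d x %d, angles %.4g..%.4g deg\n",
              length(x$angles_deg), x$geom$rows, x$geom$cols,
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Rasterize the ground-truth label volume of a phantom
#'
#' Voxel label equals the sphere label if the voxel center is inside that
#' sphere, else 0. Also reports the closed-form sphere volumes
#' `4/3 pi r^3`.
#'
#' @param phantom A [make_phantom()] scene.
#' @param grid A [grid_spec()] covering the phantom extents.
#' @return List with `labels` (3D integer array), `counts` (voxels per
#'   label), and `volumes_mm3` (analytic per-sphere volumes).
#' @export
rasterize_ground_truth <- function(phantom, grid) {
  xyz <- grid_coords(grid)
  lab <- point_sphere(phantom, xyz)
  labels <- array(lab, dim = grid$shape)
  n <- nrow(phantom$spheres)
  counts <- tabulate(lab, nbins = n)
  list(labels = labels, counts = counts,
       volumes_mm3 = sphere_volume_mm3(phantom$spheres$radius_mm))
}

#' Closed-form sphere volume
#' @param radius_mm Sphere radius in mm.
#' @return Volume in mm^3.
#' @export
sphere_volume_mm3 <- function(radius_mm) 4 / 3 * pi * radius_mm^3

#' Log-compress a dB image to display range
#'
#' Maps `[-dr_db, 0]` dB linearly onto `[0, 1]` and clips: the peak (0 dB)
#' maps to 1, anything at or below `-dr_db` to 0.
#'
#' @param image_db Image in dB (0 dB = peak).
#' @param dr_db Displayed dynamic range in dB.
#' @export
compress_dynamic_range <- function(image_db, dr_db) {
  stopifnot(dr_db > 0)
  pmin(pmax((image_db + dr_db) / dr_db, 0), 1)
}

# Run code with a temporary RNG state seeded at `seed`, restoring afterwards.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  defer_expr <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  do.call(on.exit, list(substitute(defer_expr(), list(defer_expr = defer_expr)),
                        add = TRUE), envir = env)
  invisible(seed)
}
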