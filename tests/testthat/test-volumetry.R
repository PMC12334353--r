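test_that("component labelling matches a flood-fill oracle", {
  set.seed(1)
  for (conn in c(6, 26)) {
    for (i in 1:4) {
      mask <- array(runif(16^3) < 0.25, dim = c(16, 16, 16))
      lab <- label_components(mask, conn)
      oracle <- flood_fill_labels(mask, conn)
      expect_identical(as.integer(lab), as.integer(oracle))
    }
  }
})

test_that("labelling handles disjoint objects and empty volumes", {
  m <- array(0L, c(20, 20, 20))
  m[3:6, 3:6, 3:6] <- 1L
  m[14:17, 14:17, 14:17] <- 1L
  lab <- label_components(m)
  expect_equal(attr(lab, "n_components"), 2L)
  expect_equal(label_components(array(0L, c(4, 4, 4))) |> attr("n_components"), 0L)
  # labels partition the mask: union equals mask, pairwise disjoint by construction
  expect_identical(lab > 0, m > 0)
})

test_that("convex hull volume is exact on a cube and stable under rotation", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h <- hull_mesh(cube)
  expect_false(h$degenerate)
  expect_equal(h$volume_mm3, 1, tolerance = 1e-9)
  expect_equal(nrow(h$faces), 12)     # triangulated cube
  set.seed(2)
  pts <- matrix(rnorm(300), 100, 3)
  v0 <- hull_mesh(pts)$volume_mm3
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  v1 <- hull_mesh(pts %*% Rz)$volume_mm3
  expect_equal(v1, v0, tolerance = 1e-6 * v0)
})

test_that("hull volume of a voxelized sphere approaches the analytic volume", {
  # sphere center in generic position relative to the lattice (a center
  # aligned with the grid and a radius that is an exact multiple of the
  # spacing under-fills the extreme lattice directions)
  ax <- seq(-12, 12, by = 0.5)
  g <- as.matrix(expand.grid(ax, ax, ax))
  ctr <- c(0.303, 0.365, 0.272)
  d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
  h <- hull_mesh(g[d2 < 100, ])                    # radius 10 mm
  expect_equal(h$volume_mm3, 4073.0, tolerance = 1e-9)  # frozen, oracle-checked
  expect_equal(h$volume_mm3, 4 / 3 * pi * 1000, tolerance = 0.03)
  # the hull of voxel centers slightly under-estimates the smooth ball
  expect_lt(h$volume_mm3, 4 / 3 * pi * 1000)
})

test_that("degenerate point sets yield volume zero and a flag", {
  expect_true(hull_mesh(matrix(rnorm(9), 3, 3))$degenerate)
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_true(hull_mesh(line)$degenerate)
  plane <- cbind(runif(20), runif(20), 0)
  h <- hull_mesh(plane)
  expect_true(h$degenerate)
  expect_equal(h$volume_mm3, 0)
})

test_that("dice and iou follow their counting definitions", {
  a <- c(1, 1, 1, 1, 0, 0)
  b <- c(1, 1, 0, 0, 1, 1)
  expect_equal(dice(a, b), 0.5)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  expect_equal(dice(c(1, 0), c(0, 1)), 0)
  expect_equal(iou(c(1, 0), c(0, 1)), 0)
  expect_equal(dice(c(0, 0), c(0, 0)), 1)   # both empty by convention
  expect_equal(iou(c(0, 0), c(0, 0)), 1)
})

test_that("iou equals dice / (2 - dice) for random binary masks", {
  set.seed(3)
  for (i in 1:25) {
    y <- rbinom(200, 1, runif(1, 0.1, 0.9))
    yh <- rbinom(200, 1, runif(1, 0.1, 0.9))
    d <- dice(y, yh)
    expect_equal(iou(y, yh), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("volume error is a scale-invariant percentage", {
  expect_equal(volume_error(1.0, 0.93), 7, tolerance = 1e-12)
  expect_equal(volume_error(2.5, 2.5), 0)
  expect_equal(volume_error(3 * 1.7, 3 * 1.3), volume_error(1.7, 1.3))
  expect_error(volume_error(0, 1))
})

test_that("contrast is a difference of region means, shift-invariant", {
  img <- matrix(c(-10, -10, -18, -18), 2, 2)
  expect_equal(contrast_db(img, c(1, 2), c(3, 4)), 8)
  expect_equal(contrast_db(img, c(1, 2), c(1, 2)), 0)
  expect_equal(contrast_db(img + 7, c(1, 2), c(3, 4)), 8)
  expect_error(contrast_db(img, integer(0), c(3, 4)), "empty")
})

test_that("volume metrics are exact when the prediction equals the truth", {
  g <- scan_geometry(180, 5)
  ph <- make_phantom(seed = 14, n_spheres = 3, radius_range_mm = c(6, 12),
                     geom = g)
  grid <- grid_for_geometry(g, 1)
  gt <- rasterize_ground_truth(ph, grid)
  vol <- structure(list(grid = grid,
                        intensity = array(0, dim = grid$shape),
                        mask = (gt$labels > 0) * 1L),
                   class = "voxel_volume")
  met <- volume_metrics(vol, ph)
  expect_equal(met$dice, rep(1, 3))
  expect_equal(met$iou, rep(1, 3))
  expect_equal(met$voxel_error_pct, rep(0, 3))
  expect_equal(met$pred_voxels, met$true_voxels)
  # the voxel-center hull under-estimates the smooth sphere by roughly
  # half a voxel of radius (6-11% here at 1 mm spacing)
  analytic <- sphere_volume_mm3(ph$spheres$radius_mm) / 1000
  expect_true(all(met$hull_volume_cm3 < analytic))
  expect_true(all(met$hull_volume_cm3 > 0.85 * analytic))
})

test_that("the angle-resolution study emits a tidy per-sphere table", {
  st <- acc_angle_study()
  tab <- st$table
  expect_setequal(unique(tab$step_deg), c(10, 1.25))
  per_step <- split(tab, tab$step_deg)
  for (p in per_step) {
    expect_equal(nrow(p), 5)               # 4 spheres + mean row
    expect_equal(sum(is.na(p$sphere)), 1)
    mean_row <- p[is.na(p$sphere), ]
    expect_equal(mean_row$dice, mean(p$dice[!is.na(p$sphere)]))
    expect_true(all(p$dice >= 0 & p$dice <= 1))
    expect_true(all(p$iou >= 0 & p$iou <= 1))
    expect_true(all(p$voxel_error_pct >= 0))
  }
})
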