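test_that("plan_sweep produces the half-open angle sequence", {
  a <- plan_sweep(180, 1.25)
  expect_length(a, 144)
  expect_equal(a[1], 0)
  expect_equal(a[144], 178.75)
  expect_length(plan_sweep(180, 10), 18)
  expect_length(plan_sweep(180, 5), 36)
  expect_equal(plan_sweep(180, 180), 0)
  expect_error(plan_sweep(180, 7), "7.*180|180.*7")
})

test_that("sweep count times step recovers the sweep for valid inputs", {
  for (sweep in c(90, 180, 360)) {
    for (step in c(0.5, 1.25, 2.5, 5, 9, 45)) {
      if (abs(sweep / step - round(sweep / step)) > 1e-9) next
      expect_equal(length(plan_sweep(sweep, step)) * step, sweep)
    }
  }
})

test_that("frame pixels map to world coordinates on the rotated plane", {
  g <- scan_geometry(180, 5, axial_extent_mm = 50, lateral_extent_mm = 60,
                     rows = 11, cols = 13)
  # angle 0: the frame lies in the x-y plane
  w0 <- frame_to_world(g, 0, c(0, 10, 3), c(0, 12, 5))
  expect_equal(unname(w0[, "z"]), c(0, 0, 0))
  expect_equal(unname(w0[1, ]), c(0, -30, 0))          # corner hits the bound
  expect_equal(unname(w0[2, ]), c(50, 30, 0))
  # quarter turn moves the lateral offset to z
  w90 <- frame_to_world(g, 90, 3, 5)
  l <- (5 - g$axis_col) * 60 / 12
  expect_equal(unname(w90[1, "y"]), 0, tolerance = 1e-12)
  expect_equal(unname(w90[1, "z"]), l)
  expect_error(frame_to_world(g, 0, 11, 0), "raster")
  expect_error(frame_to_world(g, 0, 0, -1), "raster")
})

test_that("radial distance is independent of the rotation angle", {
  g <- scan_geometry(180, 5, rows = 16, cols = 16)
  px <- frame_pixel_grid(g)
  r0 <- NULL
  for (th in c(0, 13.7, 90, 121, 179)) {
    w <- frame_to_world(g, th, px$rows, px$cols)
    r <- sqrt(w[, "y"]^2 + w[, "z"]^2)
    if (is.null(r0)) r0 <- r else expect_equal(r, r0, tolerance = 1e-12)
  }
})

test_that("a half-turn mirrors the in-plane offsets", {
  g <- scan_geometry(360, 5, rows = 8, cols = 8)
  px <- frame_pixel_grid(g)
  w <- frame_to_world(g, 30, px$rows, px$cols)
  w2 <- frame_to_world(g, 210, px$rows, px$cols)
  expect_equal(w2[, "y"], -w[, "y"])
  expect_equal(w2[, "z"], -w[, "z"])
  expect_equal(w2[, "x"], w[, "x"])
})

test_that("azimuthal spacing between adjacent frames grows linearly with radius", {
  g <- scan_geometry(180, 5, rows = 16, cols = 16)
  px <- frame_pixel_grid(g)
  w1 <- frame_to_world(g, 40, px$rows, px$cols)
  w2 <- frame_to_world(g, 45, px$rows, px$cols)
  r <- sqrt(w1[, "y"]^2 + w1[, "z"]^2)
  ang1 <- atan2(w1[, "z"], w1[, "y"])
  ang2 <- atan2(w2[, "z"], w2[, "y"])
  moved <- r > 1e-9
  dang <- (ang2 - ang1)[moved] %% (2 * pi)
  expect_equal(dang, rep(5 * pi / 180, sum(moved)), tolerance = 1e-9)
  # arc length = r * step in radians
  expect_equal(r[moved] * dang, r[moved] * 5 * pi / 180, tolerance = 1e-9)
})

test_that("coordinate normalization is an invertible affine map onto [-1,1]", {
  g <- scan_geometry(180, 5, axial_extent_mm = 55, lateral_extent_mm = 82,
                     rows = 64, cols = 64)
  set.seed(1)
  xyz <- cbind(runif(100, 0, 55), runif(100, -41, 41), runif(100, -41, 41))
  n <- normalize_coords(xyz, g)
  expect_true(all(abs(n) <= 1 + 1e-12))
  back <- denormalize_coords(n, g)
  expect_equal(unname(back), unname(xyz), tolerance = 1e-9)
  # frame center at half depth maps to x = 0
  ctr <- normalize_coords(cbind(27.5, 0, 0), g)
  expect_equal(unname(ctr), cbind(0, 0, 0), tolerance = 1e-12)
  # corner pixels at angle 0 land on the normalized bounds
  w <- frame_to_world(g, 0, c(0, 63), c(0, 63))
  nc <- normalize_coords(w, g)
  expect_equal(unname(nc), rbind(c(-1, -1, 0), c(1, 1, 0)), tolerance = 1e-12)
})

test_that("geometry validation rejects bad configurations", {
  expect_error(scan_geometry(180, 7), "evenly")
  expect_error(scan_geometry(0, 5))
  expect_error(scan_geometry(180, 5, rows = 1))
  expect_error(scan_geometry(180, 5, axial_extent_mm = -1))
})
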