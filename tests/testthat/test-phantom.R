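test_that("phantom generation is reproducible and respects its constraints", {
  g <- scan_geometry(180, 5)
  p1 <- make_phantom(seed = 1, geom = g)
  p2 <- make_phantom(seed = 1, geom = g)
  expect_identical(p1$spheres, p2$spheres)
  s <- p1$spheres
  expect_equal(nrow(s), 6)
  expect_true(all(s$radius_mm >= 4 & s$radius_mm <= 15))
  expect_true(all(s$contrast_db >= -2 & s$contrast_db <= 8))
  D <- as.matrix(dist(s[, c("cx", "cy", "cz")]))
  gap <- D - outer(s$radius_mm, s$radius_mm, "+")
  diag(gap) <- Inf
  expect_true(all(gap > 3))            # default placement clearance
  # spheres fully inside the swept cylinder
  expect_true(all(s$cx - s$radius_mm >= 0 & s$cx + s$radius_mm <= 55))
  expect_true(all(sqrt(s$cy^2 + s$cz^2) + s$radius_mm <= 41 + 1e-9))
})

test_that("degenerate radius range and impossible packings are handled", {
  g <- scan_geometry(180, 5)
  p <- make_phantom(seed = 2, n_spheres = 1, radius_range_mm = c(5, 5), geom = g)
  expect_equal(p$spheres$radius_mm, 5)
  expect_error(
    make_phantom(seed = 3, n_spheres = 40, radius_range_mm = c(14, 15),
                 geom = g, max_attempts = 200),
    "fewer or smaller")
})

test_that("noise-free rendering is piecewise constant at the phantom levels", {
  g <- scan_geometry(180, 5, rows = 64, cols = 64)
  p <- make_phantom(seed = 4, n_spheres = 3, geom = g, speckle_scale = 0)
  fr <- render_frame(p, g, 12.5)
  levels <- sort(unique(c(p$background_level,
                          p$background_level * 10^(p$spheres$contrast_db / 20))))
  expect_true(all(unique(as.vector(fr$intensity)) %in% levels))
  expect_true(all(fr$mask %in% c(0, 1)))
  # anechoic variant renders zero inside spheres
  pa <- make_phantom(seed = 4, n_spheres = 3, geom = g, anechoic = TRUE,
                     speckle_scale = 0)
  fa <- render_frame(pa, g, 12.5)
  expect_true(all(fa$intensity[fa$mask == 1] == 0))
})

test_that("an on-axis sphere shows the same mask disc at every angle", {
  g <- scan_geometry(180, 5, rows = 64, cols = 64)
  p <- make_phantom(seed = 6, n_spheres = 1, radius_range_mm = c(8, 8),
                    geom = g, speckle_scale = 0)
  p$spheres$cy <- 0; p$spheres$cz <- 0; p$spheres$cx <- 27.5
  areas <- vapply(c(0, 30, 77.5, 120), function(th)
    sum(render_frame(p, g, th)$mask), numeric(1))
  expect_true(max(areas) - min(areas) <= 2)  # +-1 pixel boundary jitter
})

test_that("off-plane spheres cut discs of the analytic radius", {
  # plane at distance d from the center cuts a disc of radius sqrt(r^2-d^2)
  g <- scan_geometry(180, 5, axial_extent_mm = 55, lateral_extent_mm = 82,
                     rows = 256, cols = 256)
  p <- make_phantom(seed = 7, n_spheres = 1, radius_range_mm = c(10, 10),
                    geom = g, speckle_scale = 0)
  r <- 10; d <- 4
  p$spheres$cx <- 27.5; p$spheres$cy <- 5; p$spheres$cz <- d
  fr <- render_frame(p, g, 0)          # frame plane z = 0
  pix_area <- (55 / 255) * (82 / 255)
  expect_equal(sum(fr$mask) * pix_area, pi * (r^2 - d^2), tolerance = 0.02)
})

test_that("frozen speckle is a function of world position", {
  g <- scan_geometry(180, 5, rows = 32, cols = 32)
  p <- make_phantom(seed = 8, n_spheres = 1, geom = g, speckle_scale = 1)
  f1 <- render_frame(p, g, 10)
  f2 <- render_frame(p, g, 370)        # same plane after a full turn
  expect_identical(f1$intensity, f2$intensity)
  expect_identical(f1$mask, f2$mask)
  # per-frame mode decorrelates but stays reproducible under a seed
  pf <- make_phantom(seed = 8, n_spheres = 1, geom = g, speckle_scale = 1,
                     speckle_mode = "frame")
  a <- render_frame(pf, g, 10, noise_seed = 99)
  b <- render_frame(pf, g, 10, noise_seed = 99)
  expect_identical(a$intensity, b$intensity)
})

test_that("frozen speckle envelope has unit mean and Rayleigh-like spread", {
  g <- scan_geometry(180, 5)
  p <- make_phantom(seed = 9, n_spheres = 1, geom = g)
  set.seed(10)
  xyz <- cbind(runif(20000, 0, 55), runif(20000, -30, 30), runif(20000, -30, 30))
  env <- usinr:::speckle_envelope(p, xyz)
  expect_equal(mean(env), 1, tolerance = 0.05)
  # Rayleigh with unit mean has sd sqrt(4/pi - 1) ~ 0.523
  expect_equal(sd(env), sqrt(4 / pi - 1), tolerance = 0.15)
})

test_that("masked pixel count over a sweep grows with sphere radius", {
  g <- scan_geometry(180, 15, rows = 32, cols = 32)
  count_for <- function(r) {
    p <- make_phantom(seed = 11, n_spheres = 1, radius_range_mm = c(r, r),
                      geom = g, speckle_scale = 0)
    p$spheres$cx <- 25; p$spheres$cy <- 6; p$spheres$cz <- 0
    sum(vapply(plan_sweep(g), function(th) sum(render_frame(p, g, th)$mask),
               numeric(1)))
  }
  counts <- vapply(c(5, 8, 12), count_for, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("ground-truth rasterization matches closed-form sphere volumes", {
  expect_equal(sphere_volume_mm3(0.5), pi / 6, tolerance = 1e-12)
  expect_equal(sphere_volume_mm3(6.9 / 2), 171.98, tolerance = 1e-3)

  g <- scan_geometry(180, 5)
  p <- make_phantom(seed = 12, n_spheres = 1, radius_range_mm = c(10, 10),
                    geom = g)
  errs <- vapply(c(1, 0.5), function(sp) {
    grid <- grid_spec(c(0, -41, -41), sp, floor(c(55, 82, 82) / sp) + 1)
    gt <- rasterize_ground_truth(p, grid)
    abs(gt$counts[1] * sp^3 - gt$volumes_mm3[1]) / gt$volumes_mm3[1]
  }, numeric(1))
  expect_lt(errs[2], 0.02)             # 2% at 0.5 mm spacing
  expect_lt(errs[2], errs[1])          # error shrinks as the grid refines
})

test_that("dynamic-range compression maps dB onto [0, 1] linearly", {
  expect_equal(compress_dynamic_range(0, 20), 1)
  expect_equal(compress_dynamic_range(-20, 20), 0)
  expect_equal(compress_dynamic_range(-10, 20), 0.5)
  expect_equal(compress_dynamic_range(-35, 20), 0)   # clipped at the floor
  expect_equal(compress_dynamic_range(5, 20), 1)     # clipped at the peak
  expect_error(compress_dynamic_range(0, -5))
})

test_that("frame_set validates shapes, ranges and counts", {
  g <- tiny_geom()
  ph <- make_phantom(seed = 13, n_spheres = 1, radius_range_mm = c(6, 6),
                     geom = g, speckle_scale = 0)
  fs <- render_sweep(ph, g)
  expect_s3_class(fs, "frame_set")
  expect_error(frame_set(fs$angles_deg[-1], fs$intensity, fs$mask, g),
               "count")
  bad <- fs$intensity; bad[[1]][1, 1] <- 1.5
  expect_error(frame_set(fs$angles_deg, bad, fs$mask, g), "\\[0, 1\\]")
  badm <- fs$mask; badm[[2]][1, 1] <- 0.5
  expect_error(frame_set(fs$angles_deg, fs$intensity, badm, g), "binary")
})
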