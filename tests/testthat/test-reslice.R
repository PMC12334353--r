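test_that("grid coordinates enumerate voxel centers in raster order", {
  g <- grid_spec(c(1, 2, 3), c(0.5, 1, 2), c(2, 2, 2))
  xyz <- grid_coords(g)
  expect_equal(nrow(xyz), 8)
  expect_equal(unname(xyz[1, ]), c(1, 2, 3))
  expect_equal(unname(xyz[2, ]), c(1.5, 2, 3))   # first axis varies fastest
  expect_equal(unname(xyz[3, ]), c(1, 3, 3))
  expect_equal(unname(xyz[8, ]), c(1.5, 3, 5))
  expect_error(grid_spec(c(0, 0, 0), c(0, 1, 1), c(2, 2, 2)))
})

test_that("sampling a volume tiles consistently and thresholds monotonically", {
  tf <- tiny_fit()
  model <- tf$fit$model
  one <- sample_volume(model, grid_spec(c(20, 0, 0), 1, c(1, 1, 1)))
  expect_equal(dim(one$intensity), c(1L, 1L, 1L))
  grid <- grid_spec(c(0, -20, -20), c(4, 5, 5), c(11, 9, 9))
  a <- sample_volume(model, grid)
  b <- sample_volume(model, grid, chunk = 123L)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$mask, b$mask)
  counts <- vapply(c(0.2, 0.5, 0.8), function(th)
    sum(sample_volume(model, grid, threshold = th)$mask), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(a$intensity >= 0 & a$intensity <= 1))
})

test_that("reslicing evaluates exactly the requested plane", {
  tf <- tiny_fit()
  model <- tf$fit$model
  single <- reslice(model, "x", 17, res = 1)
  direct <- inr_evaluate(model, cbind(17, 0, 0))
  expect_equal(single$intensity[1, 1],
               min(max(direct[1, "intensity"], 0), 1))
  sl <- reslice(model, "x", 17, res = 64)
  expect_equal(dim(sl$intensity), c(64L, 64L))
  # block-averaged fine reslice agrees with the coarse one in the mean
  fine <- reslice(model, "x", 17, res = 256)
  expect_equal(mean(fine$intensity), mean(sl$intensity), tolerance = 0.05)
  # oblique plane with the same frame reproduces the axis-aligned slice
  obl <- reslice_oblique(model, c(17, 0, 0), c(0, 1, 0), c(0, 0, 1),
                         extent_mm = c(40, 40), res = 32)
  expect_equal(dim(obl$intensity), c(32L, 32L))
})

test_that("nearest-neighbour interpolation is exact with deterministic ties", {
  set.seed(8)
  pts <- matrix(runif(3000), 1000, 3)
  vals <- rnorm(1000)
  q <- matrix(runif(300), 100, 3)
  got <- nn_interpolate(pts, vals, q)
  expect_identical(got, vals[brute_nn(pts, q)])
  # a query placed exactly on a datum returns that datum
  expect_identical(nn_interpolate(pts, vals, pts[17, , drop = FALSE]), vals[17])
  # idempotent on all its own sites
  expect_identical(nn_interpolate(pts, vals, pts), vals)
  # duplicated site: the lowest index wins
  dup <- rbind(c(0.5, 0.5, 0.5), pts, c(0.5, 0.5, 0.5))
  dv <- c(100, vals, 200)
  expect_identical(nn_interpolate(dup, dv, matrix(0.5, 1, 3)), 100)
  # single datum answers every query
  expect_identical(nn_interpolate(matrix(1:3, 1), 42, q), rep(42, 100))
  expect_error(nn_interpolate(matrix(numeric(0), 0, 3), numeric(0), q),
               "at least one")
})

test_that("adding a far-away datum never changes other answers", {
  set.seed(9)
  pts <- matrix(runif(300), 100, 3)
  vals <- rnorm(100)
  q <- matrix(runif(60), 20, 3)
  base <- nn_interpolate(pts, vals, q)
  far <- rbind(pts, c(100, 100, 100))
  expect_identical(nn_interpolate(far, c(vals, -1), q), base)
  # matrix-valued data interpolates per column
  vm <- cbind(vals, vals * 2)
  got <- nn_interpolate(pts, vm, q)
  expect_equal(got[, 2], 2 * got[, 1])
})

test_that("method comparison scores both reconstructions against the scene", {
  tf <- tiny_fit()
  # planes through the two sphere centers, where both methods must deliver
  tab <- compare_methods(tf$fit$model, tf$frames, tf$phantom,
                         offsets_mm = tf$phantom$spheres$cx, res = 48)
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$method), c("inr", "nn"))
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))
  expect_true(all(tab$iou <= tab$dice + 1e-12))
  expect_true(all(tab$wall_s >= 0))
  # on this noise-free scene both methods should find the spheres
  expect_true(all(tab$dice > 0.8))
})
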