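test_that("ssim is 1 on identical images, symmetric and bounded", {
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(runif(32 * 32), 32, 32)
    y <- matrix(runif(32 * 32), 32, 32)
    expect_equal(ssim(x, x), 1, tolerance = 1e-12)
    expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
    expect_lte(abs(ssim(x, y)), 1)
  }
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 5, 5)), "shapes")
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("ssim agrees with the naive sliding-window implementation", {
  set.seed(2)
  for (i in 1:3) {
    x <- matrix(runif(32 * 32), 32, 32)
    y <- matrix(runif(32 * 32), 32, 32)
    expect_equal(ssim(x, y), naive_ssim(x, y), tolerance = 1e-6)
  }
})

test_that("inverted checkerboards are structurally anti-correlated", {
  x <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  y <- 1 - x
  s <- ssim(x, y)
  expect_equal(s, naive_ssim(x, y), tolerance = 1e-6)
  expect_lt(s, 0)
  expect_gt(image_loss(x, y), 1)
})

test_that("the analytic SSIM gradient matches finite differences", {
  set.seed(3)
  x <- matrix(runif(20 * 20), 20, 20)
  y <- matrix(runif(20 * 20), 20, 20)
  g <- usinr:::cpp_ssim_grad(x, y, 11, 1e-4, 9e-4)
  h <- 1e-6
  for (idx in list(c(1, 1), c(7, 5), c(20, 20), c(10, 14))) {
    x2 <- x; x2[idx[1], idx[2]] <- x2[idx[1], idx[2]] + h
    num <- (ssim(x2, y) - ssim(x, y)) / h
    expect_equal(g$grad[idx[1], idx[2]], num, tolerance = 1e-4)
  }
})

test_that("image loss is zero iff images agree and decreases with ssim", {
  set.seed(4)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(image_loss(x, x), 0, tolerance = 1e-12)
  # blending toward the target increases ssim hence decreases the loss
  y <- matrix(runif(32 * 32), 32, 32)
  losses <- vapply(seq(0, 1, by = 0.25), function(a)
    image_loss(a * y + (1 - a) * x, y), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("segmentation loss matches its closed form on a single pixel", {
  eps <- 1e-6
  cfg <- loss_config(eps = eps)
  x <- 1 - eps; y <- 0
  s <- 1e-6
  expected <- -log(eps) + (1 - 2 * s / (x + s)) + x
  expect_equal(seg_loss(x, y, cfg), expected, tolerance = 1e-9)
  # perfect predictions sit at (numerically) zero loss
  yb <- c(0, 1, 1, 0, 1)
  expect_lt(seg_loss(yb, yb, cfg), 1e-4)
  expect_error(seg_loss(c(0.5, 1.2), c(0, 1), cfg), "\\[0, 1\\]")
  expect_error(seg_loss(c(0.5, 0.5), c(0, 2), cfg), "binary")
})

test_that("segmentation loss decreases monotonically toward the target", {
  cfg <- loss_config()
  y <- c(0, 1, 0, 1)
  x0 <- 1 - y
  losses <- vapply(seq(0, 0.98, by = 0.07), function(a)
    seg_loss(x0 + a * (y - x0), y, cfg), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("all three segmentation terms are individually non-negative", {
  set.seed(5)
  cfg <- loss_config()
  for (i in 1:20) {
    n <- 50
    x <- runif(n); y <- rbinom(n, 1, 0.4)
    xc <- pmin(pmax(x, cfg$eps), 1 - cfg$eps)
    bce <- -mean(y * log(xc) + (1 - y) * log(1 - xc))
    dice_term <- 1 - 2 * (sum(x * y) + 1e-6) / (sum(x) + sum(y) + 1e-6)
    fp <- mean(x * (1 - y))
    expect_gte(bce, 0)
    expect_gte(dice_term, -1e-9)
    expect_gte(fp, 0)
    expect_equal(seg_loss(x, y, cfg), bce + dice_term + fp, tolerance = 1e-9)
  }
})

test_that("the combined loss is linear in its components and weights", {
  cfg10 <- loss_config(w_image = 1, w_seg = 0)
  cfg01 <- loss_config(w_image = 0, w_seg = 1)
  cfg23 <- loss_config(w_image = 2, w_seg = 3)
  expect_equal(total_loss(0.4, 0.9, cfg10), 0.4)
  expect_equal(total_loss(0.4, 0.9, cfg01), 0.9)
  expect_equal(total_loss(0.4, 0.9, cfg23), 2 * 0.4 + 3 * 0.9)
})

test_that("loss configuration validates its parameters", {
  expect_error(loss_config(ssim_window = 4))
  expect_error(loss_config(ssim_window = 1))
  expect_error(loss_config(eps = 0.7))
  expect_error(loss_config(w_image = -1))
})
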