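test_that("preprocessing clips to [-30, 800] HU and standardizes", {
  arr <- array(c(-100, 0, 1000, 400), c(4, 1, 1))
  out <- preprocess_volume(image_volume(arr))
  clipped <- pmin(pmax(arr, -30), 800)
  expect_equal(out$data, (clipped - mean(clipped)) / sd(clipped))
  expect_equal(mean(out$data), 0, tolerance = 1e-9)
  # two-valued image with equal counts maps to -1 / +1 (up to sample-SD scale)
  two <- array(rep(c(-30, 800), 8), c(4, 2, 2))
  z <- preprocess_volume(image_volume(two))$data
  expect_equal(max(z), -min(z), tolerance = 1e-9)
  expect_true(all(abs(abs(z) - max(z)) < 1e-9))
  expect_error(preprocess_volume(image_volume(array(5, c(3, 3, 3)))),
               "constant")
  # clipping is rank-preserving
  expect_true(all(diff(order(out$data)) == diff(order(clipped))))
})

test_that("augmentation is seeded, label-safe, and identity at p = 0", {
  set.seed(5)
  vol <- image_volume(array(rnorm(12^3), c(12, 12, 12)),
                      spacing = c(0.5, 0.5, 0.5))
  lab <- label_map((array(rnorm(12^3), c(12, 12, 12)) > 0.5) * 1,
                   spacing = c(0.5, 0.5, 0.5))
  a1 <- augment_pair(vol, lab, seed = 7, p_blur = 1, p_affine = 1)
  a2 <- augment_pair(vol, lab, seed = 7, p_blur = 1, p_affine = 1)
  expect_identical(a1$image$data, a2$image$data)
  expect_identical(a1$labels$data, a2$labels$data)
  expect_true(all(a1$labels$data %in% c(0, 1)))
  expect_false(identical(a1$image$data, vol$data))
  a0 <- augment_pair(vol, lab, seed = 7, p_blur = 0, p_affine = 0)
  expect_identical(a0$image$data, vol$data)
})

test_that("Dice-Focal loss matches hand arithmetic and its limits", {
  y <- array(c(1, 1, 0, 0), c(2, 2, 1))
  p_half <- array(0.5, c(2, 2, 1))
  lp <- loss_params(stage = 1)
  expect_equal(lp$alpha, 0.6)
  expect_equal(lp$gamma, 2)
  expect_equal(c(lp$lambda_f, lp$lambda_d), c(1.1, 0.4))
  expect_equal(c(loss_params(stage = 2)$lambda_f,
                 loss_params(stage = 2)$lambda_d), c(0.5, 1.0))
  # hand-computed on the 2x2x1 grid: focal term is alpha (1-p)^2 log 2 on
  # positives and (1-alpha) p^2 log 2 on negatives; dice term 1 - 2*1/(2+2)
  focal_hand <- 1.1 * mean(c(rep(0.6 * 0.25 * log(2), 2),
                             rep(0.4 * 0.25 * log(2), 2)))
  dice_hand <- 0.4 * (1 - 2 * 1 / (2 + 2))
  expect_equal(dice_focal_loss(p_half, y, lp), focal_hand + dice_hand,
               tolerance = 1e-6)
  # perfect prediction: loss vanishes within clamp tolerance
  expect_lt(dice_focal_loss(y, y, lp), 1e-5)
  # pure Dice limits
  dl <- loss_params(lambda_f = 0, lambda_d = 1)
  expect_lt(dice_focal_loss(y, y, dl), 1e-6)
  disjoint <- array(c(0, 0, 1, 1), c(2, 2, 1))
  expect_equal(dice_focal_loss(disjoint, y, dl), 1, tolerance = 1e-6)
  expect_error(dice_focal_loss(array(0.5, c(3, 3)), y), "mismatch")
})

test_that("DFL is non-negative and decreases as one voxel moves toward truth", {
  set.seed(6)
  y <- as.numeric(rbinom(27, 1, 0.4))
  p <- runif(27, 0.05, 0.95)
  lp <- loss_params()
  expect_gte(dice_focal_loss(p, y, lp), 0)
  for (i in c(3, 14, 22)) {
    p2 <- p
    p2[i] <- p[i] + (if (y[i] == 1) 0.04 else -0.04)
    expect_lt(dice_focal_loss(p2, y, lp), dice_focal_loss(p, y, lp))
  }
})

test_that("multi-view fusion takes the element-wise max and is symmetric", {
  set.seed(7)
  mk <- function(x) image_volume(array(x, c(4, 4, 4)))
  a <- mk(runif(64)); b <- mk(runif(64)); cc <- mk(runif(64))
  f1 <- fuse_multiview(a, b, cc)
  f2 <- fuse_multiview(cc, a, b)
  expect_identical(f1$data, f2$data)
  expect_identical(f1$data, (pmax(a$data, b$data, cc$data) >= 0.5) * 1)
  # one confident view is enough
  lo <- mk(0.1); hi <- mk(0.9)
  expect_true(all(fuse_multiview(lo, lo, hi)$data == 1))
  # identical posteriors reduce to single-view thresholding
  expect_identical(fuse_multiview(a, a, a)$data, (a$data >= 0.5) * 1)
  expect_error(fuse_multiview(a, b, mk(runif(64) + 1)), "0, 1")
})

test_that("U-Net assembly satisfies the architecture and shape contracts", {
  m2 <- build_unet(2)
  expect_equal(m2$config$kernel, 3)
  expect_equal(m2$config$norm, "instance")
  expect_equal(sum(m2$layers$stage == "encoder"), 5)
  m3 <- build_unet(3, list(levels = 3, base_filters = 2))
  expect_equal(m3$config$kernel, 5)
  expect_equal(m3$config$norm, "batch")
  expect_equal(m3$config$in_channels, 2)

  p <- unet_forward(build_unet(2, list(base_filters = 4)),
                    matrix(rnorm(64 * 64), 64, 64))
  expect_equal(dim(p), c(64, 64))
  expect_true(all(p > 0 & p < 1))
  p3 <- unet_forward(m3, array(rnorm(16^3 * 2), c(16, 16, 16, 2)))
  expect_equal(dim(p3), c(16, 16, 16))

  expect_lt(build_unet(2, list(base_filters = 4))$n_params,
            build_unet(2, list(base_filters = 8))$n_params)
  expect_error(build_unet(2, list(levels = 0)), "depth")
  expect_error(build_unet(2, list(base_filters = 0)), "width")
  expect_error(unet_forward(m2, matrix(0, 30, 30)), "divisible")
  expect_error(unet_forward(m3, array(0, c(16, 16, 16, 1))), "channels")
})

test_that("a short training run decreases the loss deterministically", {
  phs <- smoke_train_set(4, seed = 3)
  tr1 <- smoke_train(phs, stage = 1, epochs = 2, seed = 11, n_val = 1)
  tr2 <- smoke_train(phs, stage = 1, epochs = 2, seed = 11, n_val = 1)
  expect_identical(tr1$epoch_loss, tr2$epoch_loss)
  expect_lt(tr1$epoch_loss[2], tr1$epoch_loss[1])
})
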