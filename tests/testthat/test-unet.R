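test_that("network output matches the input grid and class count", {
  m <- build_unet(tiny_cfg(seed = 1))
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  p <- woundlidar:::unet_probs(m, x)
  expect_identical(dim(p), c(32L, 32L, 2L))
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 32, 32), tolerance = 1e-5)
  # three-class stage has three score maps
  m3 <- build_unet(tiny_cfg(classes = c("other", "slough", "necrosis"),
                            in_channels = 4L, seed = 1))
  x4 <- array(runif(32 * 32 * 4), dim = c(32, 32, 4))
  expect_identical(dim(woundlidar:::unet_probs(m3, x4)), c(32L, 32L, 3L))
})

test_that("input sizes must be divisible by 2^depth_levels", {
  expect_error(seg_config(input_size = c(100, 100), depth_levels = 3),
               "divisible")
  m <- build_unet(tiny_cfg(seed = 1))
  x <- array(runif(30 * 30 * 3), dim = c(30, 30, 3))
  expect_error(woundlidar:::unet_probs(m, x), "divisible")
})

test_that("parameter count strictly increases with base filters", {
  n <- sapply(c(4L, 8L, 16L), function(f)
    n_params(build_unet(tiny_cfg(base_filters = f, seed = 1))))
  expect_true(all(diff(n) > 0))
})

test_that("dice and iou match their closed forms and inequalities", {
  a <- matrix(FALSE, 20, 20); b <- a
  a[1:10, 1:10] <- TRUE            # 100 px
  b[6:15, 1:10] <- TRUE            # 100 px, overlap 50
  expect_equal(dice(a, b), 0.5)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  d <- matrix(FALSE, 20, 20); d[16:20, 16:20] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(iou(a, d), 0)
  # empty vs empty is defined as 1
  e <- matrix(FALSE, 5, 5)
  expect_equal(dice(e, e), 1)
  expect_equal(iou(e, e), 1)
  expect_error(dice(a, matrix(TRUE, 3, 3)), "shapes differ")
  # properties over random masks: symmetric, bounded, dice >= iou
  set.seed(1)
  for (i in 1:25) {
    m1 <- matrix(runif(64) > runif(1), 8, 8)
    m2 <- matrix(runif(64) > runif(1), 8, 8)
    expect_equal(dice(m1, m2), dice(m2, m1))
    expect_equal(iou(m1, m2), iou(m2, m1))
    expect_gte(dice(m1, m2), iou(m1, m2))
    expect_true(dice(m1, m2) >= 0 && dice(m1, m2) <= 1)
  }
})

test_that("tissue fractions and presence calls follow their definitions", {
  mask <- matrix(TRUE, 8, 8)
  allslough <- matrix(1L, 8, 8)
  f <- tissue_fractions(allslough, mask)
  expect_equal(c(f$slough_pct, f$necrosis_pct), c(100, 0))
  t2 <- matrix(0L, 8, 8); t2[1:2, 1:8] <- 1L; t2[3, 1:8] <- 2L
  f2 <- tissue_fractions(t2, mask)
  expect_equal(c(f2$slough_pct, f2$necrosis_pct), c(25, 12.5))
  # empty wound bed
  f0 <- tissue_fractions(matrix(0L, 8, 8), matrix(FALSE, 8, 8))
  expect_equal(c(f0$slough_pct, f0$necrosis_pct, f0$wound_pixels), c(0, 0, 0))
  # presence threshold: trace slough absent, clear necrosis present
  fx <- structure(list(slough_pct = 0.03, necrosis_pct = 8.17,
                       wound_pixels = 1000L), class = "tissue_fractions")
  pc <- presence_call(fx)
  expect_false(pc$slough_present)
  expect_true(pc$necrosis_present)
  expect_false(presence_call(f0)$slough_present)
  # zero threshold counts any nonzero sliver
  expect_true(presence_call(fx, threshold_pct = 0)$slough_present)
})

test_that("stage-2 predictions never leak outside the wound mask", {
  m3 <- build_unet(tiny_cfg(classes = c("other", "slough", "necrosis"),
                            in_channels = 4L, seed = 2))
  rgb <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  mask <- matrix(FALSE, 32, 32); mask[8:20, 8:20] <- TRUE
  tm <- segment_tissue(m3, rgb, mask)   # untrained: contract must still hold
  expect_true(all(tm[!mask] == 0))
  # empty mask is valid and yields an empty tissue map
  tm0 <- segment_tissue(m3, rgb, matrix(FALSE, 32, 32))
  expect_true(all(tm0 == 0))
})

test_that("masks resized for inference keep their area fraction", {
  m <- build_unet(tiny_cfg(seed = 3))
  rgb <- array(runif(48 * 40 * 3), dim = c(48, 40, 3))
  mask <- segment_wound(m, rgb)
  expect_identical(dim(mask), c(48L, 40L))
  # round-trip of a known mask through the resize helper
  big <- matrix(FALSE, 192, 256); big[40:120, 60:200] <- TRUE
  small <- woundlidar:::resize_nearest(big, c(128, 128))
  back <- woundlidar:::resize_nearest(small, c(192, 256))
  expect_lt(abs(mean(back) - mean(big)), 0.01)
})

test_that("training is seeded-reproducible and early stopping obeys patience", {
  ds <- generate_dataset(12, seed = 3, image_size = c(32, 32))
  cfg <- tiny_cfg(max_epochs = 3, seed = 7)
  h1 <- train_unet(build_unet(cfg), ds, stage = 1)$history
  h2 <- train_unet(build_unet(cfg), ds, stage = 1)$history
  expect_identical(h1, h2)
  expect_identical(nrow(h1), 3L)
  # a fully plateaued run (frozen weights) stops after exactly the patience
  cfg0 <- tiny_cfg(learning_rate = 0, max_epochs = 40,
                   early_stop_patience = 10L, seed = 1)
  m0 <- train_unet(build_unet(cfg0), ds, stage = 1)
  expect_identical(nrow(m0$history), 11L)   # best at 1 + 10 patience epochs
  expect_identical(m0$best_epoch, 1L)
})

test_that("a briefly trained stage-1 net finds high-contrast wounds", {
  ds <- generate_dataset(24, seed = 21, image_size = c(32, 32), p_empty = 0)
  cfg <- seg_config(input_size = c(32, 32), depth_levels = 2L,
                    base_filters = 8L, max_epochs = 10, seed = 2)
  m <- train_unet(build_unet(cfg), ds, stage = 1)
  expect_gt(max(m$history$val_dice), 0.5)
  # best-epoch weights are the ones kept
  expect_identical(m$best_epoch, which.min(m$history$val_loss))
})
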