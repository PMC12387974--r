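test_that("back-projection maps pixels to metric points by similar triangles", {
  cam <- camera_model(focal_length_px = 250, image_size = c(101, 101),
                      principal_point = c(50, 50))
  # on-axis ray: pixel at the principal point with z = 300 -> (0, 0, 300)
  v <- matrix(NA_real_, 101, 101)
  v[51, 51] <- 300
  pts <- backproject(depth_map(v, measurement = "z"), cam)
  expect_equal(unname(pts[1, c("x", "y", "z")]), c(0, 0, 300))
  # 50 columns right of the center at z = 300: x = 50 * 300 / 250 = 60
  v2 <- matrix(NA_real_, 101, 101)
  v2[51, 101] <- 300
  pts2 <- backproject(depth_map(v2, measurement = "z"), cam)
  expect_equal(unname(pts2[1, "x"]), 60)
  expect_equal(unname(pts2[1, "z"]), 300)
  # sensor-native range measurements divide by the ray norm first
  rng <- 300 * sqrt(1 + (50 / 250)^2)
  v3 <- matrix(NA_real_, 101, 101)
  v3[51, 101] <- rng
  pts3 <- backproject(depth_map(v3, measurement = "range"), cam)
  expect_equal(unname(pts3[1, c("x", "z")]), c(60, 300), tolerance = 1e-12)
})

test_that("projection of back-projected points returns the pixel centers", {
  cam <- std_cam()
  dm <- render_lidar(cavity_scene(depth = 12, edge = 70), cam, noise_sd = 0)
  pts <- backproject(dm, cam)
  px <- project_points(pts, cam)
  expect_lt(max(abs(px[, "row"] - pts[, "row"])), 1e-6)
  expect_lt(max(abs(px[, "col"] - pts[, "col"])), 1e-6)
})

test_that("backproject validates inputs", {
  cam <- camera_model(image_size = c(8, 8))
  expect_error(backproject(depth_map(matrix(NA_real_, 8, 8)), cam),
               "no valid returns")
  expect_error(backproject(depth_map(matrix(300, 4, 4)), cam), "shape")
})

test_that("pixel footprint is (z/f)^2 and scales quadratically", {
  cam <- camera_model(focal_length_px = 250)
  expect_equal(pixel_footprint(300, cam), 1.44)
  expect_equal(pixel_footprint(600, cam), 5.76)
  z <- runif(20, 100, 900)
  k <- runif(20, 0.2, 5)
  expect_equal(pixel_footprint(k * z, cam), k^2 * pixel_footprint(z, cam))
  expect_error(pixel_footprint(0, cam), "> 0")
  expect_error(pixel_footprint(-5, cam), "> 0")
})

test_that("footprint summation over a flat rendered patch recovers its area", {
  cam <- std_cam()
  # 40 x 40 mm flat opening rendered as a shallow (0.5 mm) wound
  sc <- cavity_scene(aperture = 40, depth = 0.5, edge = 90)
  gt <- render_ground_truth(sc, cam)
  dm <- render_lidar(sc, cam, noise_sd = 0)
  area <- compute_wound_area(gt$wound_mask, dm, cam, angle_adjust = FALSE)
  expect_lt(abs(area$area_cm2 - 16) / 16, 0.02)
})

test_that("total least squares plane fit recovers exact and noisy planes", {
  # exact fronto-parallel plane
  g <- expand.grid(x = seq(-20, 20, 5), y = seq(-20, 20, 5))
  pl <- fit_plane(cbind(x = g$x, y = g$y, z = 300))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$offset, 300)
  expect_equal(pl$rms_residual, 0, tolerance = 1e-10)
  expect_identical(pl$n_support_points, as.integer(nrow(g)))
  # any 3 non-collinear points are interpolated exactly
  tri <- rbind(c(0, 0, 300), c(10, 2, 305), c(-3, 8, 298))
  colnames(tri) <- c("x", "y", "z")
  expect_lt(fit_plane(tri)$rms_residual, 1e-10)
  # 20-degree tilted plane + noise sd 0.5 mm: tilt recovered within 1 degree
  set.seed(42)
  n <- 500
  x <- runif(n, -30, 30); y <- runif(n, -30, 30)
  z <- 350 + y * tan(20 * pi / 180) + rnorm(n, 0, 0.5)
  pln <- fit_plane(cbind(x = x, y = y, z = z))
  expect_lt(abs(plane_tilt_deg(pln) - 20), 1)
})

test_that("plane fit is invariant to point order and rigid translation", {
  set.seed(7)
  pts <- cbind(x = runif(50, -20, 20), y = runif(50, -20, 20), z = 0)
  pts[, "z"] <- 300 + 0.3 * pts[, "x"] + rnorm(50, 0, 0.2)
  p1 <- fit_plane(pts)
  p2 <- fit_plane(pts[sample(50), ])
  expect_equal(p1$normal, p2$normal)
  expect_equal(p1$offset, p2$offset)
  shift <- c(5, -3, 40)
  p3 <- fit_plane(sweep(pts, 2, -shift))
  expect_equal(p3$normal, p1$normal, tolerance = 1e-9)
  expect_equal(p3$offset, p1$offset + sum(p1$normal * shift),
               tolerance = 1e-9)
})

test_that("plane fit rejects degenerate geometry", {
  expect_error(fit_plane(rbind(c(0, 0, 1), c(1, 1, 1))), "at least 3")
  line <- cbind(x = 1:10, y = 2 * (1:10), z = 3 * (1:10))
  expect_error(fit_plane(line), "collinear")
})

test_that("plane refit through render round trip recovers the skin plane", {
  cam <- std_cam()
  dm <- render_lidar(cavity_scene(depth = 0), cam, noise_sd = 0)
  pl <- fit_plane(backproject(dm, cam))
  expect_lt(abs(pl$offset - 350), 0.1)
  expect_lt(plane_tilt_deg(pl), 0.01)
})

test_that("bilinear upsampling is smooth, bounded and sentinel-preserving", {
  # the sensor-native 192 x 256 map morphs to 512 x 683
  dm <- render_lidar(cavity_scene(depth = 8), std_cam(), noise_sd = 0)
  up <- upsample_depth(dm, c(512, 683))
  expect_identical(dim(up), c(512L, 683L))
  expect_gte(min(up, na.rm = TRUE), min(dm, na.rm = TRUE))
  expect_lte(max(up, na.rm = TRUE), max(dm, na.rm = TRUE))
  # constant map stays constant
  cst <- upsample_depth(depth_map(matrix(123.4, 6, 8)), c(20, 30))
  expect_equal(max(abs(cst - 123.4)), 0, tolerance = 1e-12)
  # a ramp is reproduced exactly at node-aligned target pixels
  src <- depth_map(outer(seq(100, 200, length.out = 5),
                         seq(0, 40, length.out = 9), `+`))
  up2 <- upsample_depth(src, c(9, 17))  # every source node lands on a pixel
  expect_equal(up2[seq(1, 9, 2), seq(1, 17, 2)], unclass(src),
               tolerance = 1e-6, ignore_attr = TRUE)
  # missing regions propagate
  v <- matrix(200, 10, 10); v[4, 5] <- NA
  upna <- upsample_depth(depth_map(v), c(19, 19))
  expect_true(any(is.na(upna)))
  expect_true(is.na(upna[7, 9]))  # the node-aligned copy of the NA pixel
  # refusal to downsample
  expect_error(upsample_depth(src, c(4, 9)), "at least the source size")
})
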