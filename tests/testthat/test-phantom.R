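test_that("cavity height field follows the adjustable-cube geometry", {
  # vertical walls: flat floor the full aperture wide, 10 mm below skin
  s1 <- cavity_scene(aperture = 40, depth = 10, edge = 90)
  expect_equal(scene_height(s1, 0, 0), -10)
  expect_equal(scene_height(s1, 19.9, 0), -10)   # still inside
  expect_equal(scene_height(s1, 20.1, 0), 0)     # outside the opening
  # walls meet exactly: aperture 20, depth 10, edge 45 -> V apex at -10
  s2 <- cavity_scene(aperture = 20, depth = 10, edge = 45)
  expect_equal(scene_height(s2, 0, 0), -10)
  expect_equal(scene_height(s2, 5, 0), -5)       # on the 45-degree wall
  # hypergranulation: depth -4 -> bump rising 4 mm above skin
  s3 <- cavity_scene(aperture = 40, depth = -4, edge = 60)
  u <- seq(-25, 25, 0.5)
  expect_equal(max(scene_height(s3, u, 0)), 4)
  expect_gte(min(scene_height(s3, u, 0)), 0)
  # invalid parameters
  expect_error(phantom_spec(aperture = 0), "aperture")
  expect_error(phantom_spec(edge_angle_deg = 0), "edge_angle_deg")
  expect_error(phantom_spec(skin_distance = -1), "skin_distance")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("noise-free rendering returns exact ray-plane ranges on flat skin", {
  cam <- std_cam()
  dm <- render_lidar(cavity_scene(depth = 0), cam, noise_sd = 0)
  r <- c(1, 50, 96, 192); cc <- c(1, 100, 128, 256)
  for (i in r) for (j in cc) {
    d <- c((j - 1 - cam$principal_point[2]) / cam$focal_length_px,
           (i - 1 - cam$principal_point[1]) / cam$focal_length_px, 1)
    expect_equal(dm[i, j], 350 * sqrt(sum(d^2)), tolerance = 1e-9)
  }
})

test_that("rendering is bit-identical for a fixed seed", {
  sc <- make_cavity_scene(phantom_spec(aperture = 30, true_depth = 8,
                                       noise_sd = 1, seed = 99))
  d1 <- render_lidar(sc, std_cam())
  d2 <- render_lidar(sc, std_cam())
  expect_identical(unclass(d1), unclass(d2))
  d3 <- render_lidar(sc, std_cam(), seed = 100)
  expect_false(identical(unclass(d1), unclass(d3)))
})

test_that("ray-cast ranges match the dense-sampling oracle within 0.05 mm", {
  cam <- std_cam()
  scenes <- list(
    cavity_scene(aperture = 40, depth = 10, edge = 90),
    cavity_scene(aperture = 30, depth = 12, edge = 50, shape = "elliptical"),
    cavity_scene(aperture = 20, depth = 10, edge = 45),
    cavity_scene(aperture = 12, depth = 35, edge = 80),
    cavity_scene(aperture = 25, depth = -6, edge = 70, shape = "elliptical",
                 tilt = 12))
  for (sc in scenes) {
    dm <- render_lidar(sc, cam, noise_sd = 0)
    row <- 96  # cross-section through the wound center
    for (col in seq(104, 152, by = 6)) {
      o <- oracle_range(sc, cam, row - 1, col - 1)
      expect_lt(abs(dm[row, col] - o), 0.05)
    }
  }
})

test_that("cavities deepen ranges and bumps shorten them (noise off)", {
  cam <- std_cam()
  flat <- render_lidar(cavity_scene(depth = 0), cam, noise_sd = 0)
  for (d in c(6, -6)) {
    sc <- cavity_scene(aperture = 36, depth = d, edge = 75)
    dm <- render_lidar(sc, cam, noise_sd = 0)
    gt <- render_ground_truth(sc, cam)
    inside <- gt$wound_mask
    if (d > 0) expect_true(all(dm[inside] >= flat[inside] - 1e-9))
    else expect_true(all(dm[inside] <= flat[inside] + 1e-9))
    expect_equal(unclass(dm)[!inside], unclass(flat)[!inside],
                 tolerance = 1e-9)
  }
})

test_that("floor visibility shrinks as edges steepen into the failure regime", {
  cam <- std_cam()
  skin_rng <- unclass(render_lidar(cavity_scene(depth = 0), cam,
                                   noise_sd = 0))
  # fraction of wound pixels seeing at least 80% of the set depth
  vis_frac <- sapply(c(90, 70, 50, 40, 30, 20), function(e) {
    sc <- cavity_scene(aperture = 30, depth = 12, edge = e)
    dm <- render_lidar(sc, cam, noise_sd = 0)
    gt <- render_ground_truth(sc, cam)
    depth_seen <- unclass(dm)[gt$wound_mask] - skin_rng[gt$wound_mask]
    mean(depth_seen > 0.8 * 12)
  })
  expect_true(all(diff(vis_frac) <= 1e-9))
  # deep narrow cavity: not all of the floor depth is observable
  scd <- cavity_scene(aperture = 12, depth = 35, edge = 80)
  dmd <- render_lidar(scd, cam, noise_sd = 0)
  skin <- render_lidar(cavity_scene(depth = 0), cam, noise_sd = 0)
  expect_lt(max(unclass(dmd) - unclass(skin), na.rm = TRUE), 35)
})

test_that("ground-truth tissue maps honour the layout fractions", {
  cam <- std_cam()
  sc <- cavity_scene(aperture = 50, depth = 5,
                     layout = tissue_layout(0.5, 0, seed = 3))
  rr <- render_rgb(sc, cam)
  tf <- tissue_fractions(rr$tissue_map, rr$wound_mask)
  expect_lt(abs(tf$slough_pct - 50), 5)
  expect_equal(tf$necrosis_pct, 0)
  # no devitalized tissue requested -> none painted
  sc0 <- cavity_scene(aperture = 50, depth = 5,
                      layout = tissue_layout(0, 0))
  rr0 <- render_rgb(sc0, cam)
  expect_true(all(rr0$tissue_map == 0))
  # patch geometry varies by seed, aggregate fractions do not
  fr <- sapply(1:20, function(s) {
    scs <- cavity_scene(aperture = 50, depth = 5,
                        layout = tissue_layout(0.4, 0.2, seed = s))
    gt <- render_ground_truth(scs, cam)
    f <- tissue_fractions(gt$tissue_map, gt$wound_mask)
    c(f$slough_pct, f$necrosis_pct,
      sum(gt$tissue_map == 1 & gt$wound_mask))
  })
  expect_true(all(abs(fr[1, ] - 40) < 5))
  expect_true(all(abs(fr[2, ] - 20) < 5))
  # labels only inside the mask
  gt <- render_ground_truth(sc, cam)
  expect_true(all(gt$tissue_map[!gt$wound_mask] == 0))
})

test_that("datasets split 70/20/10, disjoint and exhaustive, reproducibly", {
  ds <- generate_dataset(100, seed = 5, image_size = c(32, 32))
  expect_identical(as.integer(table(ds$manifest$split)[c("train",
                                                         "validation",
                                                         "test")]),
                   c(70L, 20L, 10L))
  ds10 <- generate_dataset(10, seed = 5, image_size = c(32, 32))
  expect_identical(as.integer(table(ds10$manifest$split)[c("train",
                                                           "validation",
                                                           "test")]),
                   c(7L, 2L, 1L))
  idx <- c(dataset_split(ds10, "train"), dataset_split(ds10, "validation"),
           dataset_split(ds10, "test"))
  expect_identical(sort(idx), 1:10)
  ds10b <- generate_dataset(10, seed = 5, image_size = c(32, 32))
  expect_identical(ds10$manifest, ds10b$manifest)
  expect_identical(ds10$images, ds10b$images)
  expect_error(generate_dataset(9), ">= 10")
})

test_that("bench sweep produces one row per render and is exact without noise", {
  tab <- sweep_invitro(depths = c(8, 14), edge_angles = c(60, 90),
                       repeats = 3, seed = 2, noise_sd = 0)
  expect_identical(nrow(tab), 12L)
  # noise off: zero variance across repeats of a configuration
  v <- tapply(tab$est_depth, tab$config, function(x) diff(range(x)))
  expect_true(all(v == 0))
  expect_error(sweep_invitro(numeric(0), edge_angles = 90), "empty")
})
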