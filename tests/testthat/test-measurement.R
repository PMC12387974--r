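test_that("flat elliptical wound area matches the analytic pi*a*b", {
  cam <- std_cam()
  sc <- cavity_scene(aperture = 40, depth = 0.5, edge = 90,
                     shape = "elliptical")
  gt <- render_ground_truth(sc, cam)
  dm <- render_lidar(sc, cam, noise_sd = 0)
  res <- compute_wound_area(gt$wound_mask, dm, cam)
  expect_lt(abs(res$area_cm2 - pi * 4) / (pi * 4), 0.02)
  expect_identical(res$n_pixels, as.integer(sum(gt$wound_mask)))
  # empty mask -> zero area
  empty <- compute_wound_area(matrix(FALSE, 192, 256), dm, cam)
  expect_identical(empty$area_cm2, 0)
  expect_identical(empty$n_pixels, 0L)
})

test_that("area is invariant to capture distance between 300 and 500 mm", {
  cam <- std_cam()
  # a 60 mm opening stays well resolved (>600 px) across the whole range;
  # much smaller wounds at 500 mm are dominated by pixel rasterization
  areas <- sapply(c(300, 400, 500), function(D) {
    sc <- make_cavity_scene(phantom_spec(skin_distance = D, aperture = 60,
                                         true_depth = 0.5,
                                         shape = "elliptical", noise_sd = 0))
    gt <- render_ground_truth(sc, cam)
    dm <- render_lidar(sc, cam, noise_sd = 0)
    compute_wound_area(gt$wound_mask, dm, cam)$area_cm2
  })
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
})

test_that("angle adjustment undoes cos(theta) foreshortening", {
  cam <- std_cam()
  sc <- cavity_scene(aperture = 40, depth = 0.5, edge = 90,
                     shape = "elliptical", tilt = 30)
  gt <- render_ground_truth(sc, cam)
  dm <- render_lidar(sc, cam, noise_sd = 0)
  on <- compute_wound_area(gt$wound_mask, dm, cam, angle_adjust = TRUE)
  off <- compute_wound_area(gt$wound_mask, dm, cam, angle_adjust = FALSE)
  expect_true(on$tilt_correction_applied)
  expect_false(off$tilt_correction_applied)
  expect_lt(abs(off$area_cm2 / on$area_cm2 - cos(30 * pi / 180)), 0.02)
  # the adjusted area is the physical one
  expect_lt(abs(on$area_cm2 - pi * 4) / (pi * 4), 0.03)
})

test_that("reference surface recovers the generating skin plane", {
  cam <- std_cam()
  sc <- cavity_scene(aperture = 40, depth = 10)
  gt <- render_ground_truth(sc, cam)
  dm <- render_lidar(sc, cam, noise_sd = 0)
  pl <- reconstruct_reference_surface(gt$wound_mask, dm, cam)
  expect_lt(abs(pl$offset - 350), 0.2)
  expect_lt(plane_tilt_deg(pl), 0.5)
  # tilted skin: recovered tilt within 1 degree
  sct <- cavity_scene(aperture = 40, depth = 10, tilt = 15)
  gtt <- render_ground_truth(sct, cam)
  dmt <- render_lidar(sct, cam, noise_sd = 0)
  expect_lt(abs(plane_tilt_deg(
    reconstruct_reference_surface(gtt$wound_mask, dmt, cam)) - 15), 1)
})

test_that("a boundary ring clipped by the image border is rejected", {
  cam <- std_cam()
  sc <- cavity_scene(aperture = 40, depth = 5)
  dm <- render_lidar(sc, cam, noise_sd = 0)
  # a mask running off every border leaves no healthy-skin ring at all
  mask <- matrix(TRUE, 192, 256)
  expect_error(reconstruct_reference_surface(mask, dm, cam),
               "degenerate boundary")
  expect_error(reconstruct_reference_surface(matrix(FALSE, 192, 256),
                                             dm, cam),
               "degenerate boundary")
})

test_that("wound depth recovers cavities, bumps and the resolution floor", {
  cam <- std_cam()
  # 10 mm cavity, wide opening, vertical walls
  sc <- cavity_scene(aperture = 50, depth = 10)
  gt <- render_ground_truth(sc, cam)
  dr <- estimate_wound_depth(gt$wound_mask,
                             render_lidar(sc, cam, noise_sd = 0), cam)
  expect_false(dr$sentinel)
  expect_lt(abs(dr$depth_mm - 10), 0.5)
  expect_identical(length(dr$deepest_pixel), 2L)
  # 2 mm cavity is below the +/-3 mm floor
  scs <- cavity_scene(aperture = 40, depth = 2)
  gts <- render_ground_truth(scs, cam)
  drs <- estimate_wound_depth(gts$wound_mask,
                              render_lidar(scs, cam, noise_sd = 0), cam)
  expect_true(drs$sentinel)
  expect_identical(drs$depth_mm, 0)
  expect_lt(abs(drs$extremum_mm), 3)
  expect_identical(format_depth(drs), "+/-3")
  # 4 mm hypergranulation bump -> negative depth
  scb <- cavity_scene(aperture = 40, depth = -4, edge = 60)
  gtb <- render_ground_truth(scb, cam)
  drb <- estimate_wound_depth(gtb$wound_mask,
                              render_lidar(scb, cam, noise_sd = 0), cam)
  expect_false(drb$sentinel)
  expect_lt(abs(drb$depth_mm - (-4)), 0.5)
})

test_that("sentinel fires exactly below 3 mm on noise-free phantoms", {
  cam <- std_cam()
  for (d in c(1, 2.4, 2.9)) {
    sc <- cavity_scene(aperture = 40, depth = d)
    gt <- render_ground_truth(sc, cam)
    expect_true(estimate_wound_depth(
      gt$wound_mask, render_lidar(sc, cam, noise_sd = 0), cam)$sentinel)
  }
  for (d in c(3.5, 5, 8)) {
    sc <- cavity_scene(aperture = 40, depth = d)
    gt <- render_ground_truth(sc, cam)
    expect_false(estimate_wound_depth(
      gt$wound_mask, render_lidar(sc, cam, noise_sd = 0), cam)$sentinel)
  }
})

test_that("deep narrow cavities are strictly underestimated", {
  cam <- std_cam()
  sc <- cavity_scene(aperture = 12, depth = 35, edge = 80)
  gt <- render_ground_truth(sc, cam)
  dr <- estimate_wound_depth(gt$wound_mask,
                             render_lidar(sc, cam, noise_sd = 0), cam)
  expect_lt(dr$depth_mm, 35)
})

test_that("depth never overshoots the set depth by more than noise allows", {
  cam <- std_cam()
  for (s in 1:5) {
    sc <- cavity_scene(aperture = 46, depth = 12)
    gt <- render_ground_truth(sc, cam)
    dm <- render_lidar(sc, cam, noise_sd = 1, seed = s)
    dr <- estimate_wound_depth(gt$wound_mask, dm, cam)
    expect_lt(dr$depth_mm, 12 + 3 * 1 + 0.1)
  }
})

test_that("measure() assembles a deterministic end-to-end report", {
  cam <- std_cam()
  sc <- make_cavity_scene(phantom_spec(aperture = 40, true_depth = 10,
                                       shape = "elliptical", noise_sd = 0),
                          tissue_layout(0.4, 0.1, seed = 4))
  gt <- render_ground_truth(sc, cam)
  dm <- render_lidar(sc, cam, noise_sd = 0)
  rep <- measure(dm, cam, mask = gt$wound_mask, tissue = gt$tissue_map)
  expect_s3_class(rep, "wound_report")
  expect_false(rep$depth$sentinel)
  expect_lt(abs(rep$depth$depth_mm - 10), 0.5)
  expect_lt(abs(rep$tissue_fractions$slough_pct - 40), 5)
  j1 <- write_report(rep)
  j2 <- write_report(measure(dm, cam, mask = gt$wound_mask,
                             tissue = gt$tissue_map))
  expect_identical(j1, j2)
  # errors carry the failing stage
  bad <- matrix(TRUE, 192, 256)
  expect_error(measure(dm, cam, mask = bad), "area stage|degenerate")
})
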