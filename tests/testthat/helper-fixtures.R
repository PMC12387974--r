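# Shared fixtures: a standard sensor, quick phantom builders, and an
# independent dense-sampling first-hit oracle used to validate the analytic
# ray caster.

std_cam <- function() camera_model()

cavity_scene <- function(aperture = 40, depth = 10, edge = 90,
                         shape = "rectangular", tilt = 0, layout = NULL,
                         offset = c(0, 0)) {
  make_cavity_scene(
    phantom_spec(aperture = aperture, true_depth = depth,
                 edge_angle_deg = edge, shape = shape, skin_tilt_deg = tilt,
                 center_offset = offset, noise_sd = 0),
    layout)
}

# First-hit range for the ray of (0-based) pixel (r, c): dense forward
# sampling of w(t) - height(u(t), v(t)) followed by bisection. Shares only
# the scene height definition with the renderer, not its intersection logic.
oracle_range <- function(scene, cam, r, c, tmax = 1200, step = 0.05) {
  sp <- scene$spec
  th <- sp$skin_tilt_deg * pi / 180
  f <- cam$focal_length_px
  d <- c((c - cam$principal_point[2]) / f,
         (r - cam$principal_point[1]) / f, 1)
  dn <- sqrt(sum(d^2))
  eu <- c(1, 0, 0); ev <- c(0, cos(th), sin(th)); m <- c(0, sin(th), -cos(th))
  P0 <- c(0, 0, sp$skin_distance)
  g <- function(t) {
    p <- t * d
    sum((p - P0) * m) - scene_height(scene, sum((p - P0) * eu),
                                     sum((p - P0) * ev))
  }
  ts <- seq(1, tmax, by = step)
  gs <- vapply(ts, g, numeric(1))
  i <- which(gs <= 0)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  lo <- ts[i - 1]; hi <- ts[i]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) * dn
}

# Tiny U-Net setup used by contract tests (not quality tests).
tiny_cfg <- function(...) {
  args <- modifyList(list(input_size = c(32L, 32L), depth_levels = 2L,
                          base_filters = 4L),
                     list(...))
  do.call(seg_config, args)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() {
  system.file("cli", "woundlidar.R", package = "woundlidar")
}

run_cli <- function(args) {
  suppressWarnings(system2(rscript_bin(), c(cli_script(), args),
                           stdout = TRUE, stderr = TRUE))
}
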