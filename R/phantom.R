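#' Parametric in-vitro wound phantom
#'
#' Describes the adjustable-cube bench phantom used to validate depth
#' sensing: a flat "skin" plane with a wound opening whose walls descend at a
#' fixed steepness to a flat floor. Pushing the cubes together narrows the
#' aperture while deepening the cavity, so the floor width is
#' `aperture - 2 * true_depth / tan(edge_angle_deg)`; when that is <= 0 the
#' walls meet in a V-profile and the achievable cavity depth is capped at
#' `tan(edge_angle_deg) * aperture / 2`. A negative `true_depth` models
#' hypergranulation: a bump of that height rising above the skin instead of
#' a cavity.
#'
#' @param skin_distance Camera-to-skin distance along the optical axis, mm.
#' @param aperture Wound opening `(width, length)` at skin level in mm; a
#'   scalar is used for both.
#' @param true_depth Cavity depth in mm (>= 0), or negative bump height.
#' @param edge_angle_deg Wall steepness in degrees from the skin plane
#'   (90 = vertical walls); must be in (0, 90].
#' @param shape `"rectangular"` or `"elliptical"` opening.
#' @param skin_tilt_deg Tilt of the skin plane about the camera x-axis,
#'   degrees.
#' @param center_offset In-plane `(u, v)` offset of the wound center from the
#'   optical-axis intersection, mm.
#' @param noise_sd Per-pixel Gaussian range-noise standard deviation, mm.
#' @param seed Integer seed for the rendering noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(skin_distance = 350, aperture = c(40, 40),
                         true_depth = 10, edge_angle_deg = 90,
                         shape = c("rectangular", "elliptical"),
                         skin_tilt_deg = 0, center_offset = c(0, 0),
                         noise_sd = 1, seed = 1L) {
  shape <- match.arg(shape)
  if (length(aperture) == 1) aperture <- rep(aperture, 2)
  if (skin_distance <= 0) stop("skin_distance must be > 0")
  if (any(aperture <= 0)) stop("aperture components must be > 0")
  if (edge_angle_deg <= 0 || edge_angle_deg > 90)
    stop("edge_angle_deg must be in (0, 90]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(skin_distance = skin_distance,
                 aperture = as.numeric(aperture),
                 true_depth = as.numeric(true_depth),
                 edge_angle_deg = as.numeric(edge_angle_deg),
                 shape = shape,
                 skin_tilt_deg = as.numeric(skin_tilt_deg),
                 center_offset = as.numeric(center_offset),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Target tissue composition for a synthetic wound
#'
#' Controls the ground-truth tissue map painted inside the wound opening of a
#' synthetic wound photo: target area fractions of slough and necrosis (the
#' remainder is granulation/"other"), and the spatial correlation length of
#' the tissue patches.
#'
#' @param slough_fraction Target fraction of wound pixels labelled slough.
#' @param necrosis_fraction Target fraction labelled necrosis;
#'   `slough_fraction + necrosis_fraction` must be <= 1.
#' @param patch_granularity Patch correlation length in rendered pixels.
#' @param seed Integer seed for the patch field.
#' @return An object of class `tissue_layout`.
#' @export
tissue_layout <- function(slough_fraction = 0.3, necrosis_fraction = 0.1,
                          patch_granularity = 16, seed = 1L) {
  if (slough_fraction < 0 || necrosis_fraction < 0)
    stop("tissue fractions must be >= 0")
  if (slough_fraction + necrosis_fraction > 1)
    stop("slough_fraction + necrosis_fraction must be <= 1")
  if (patch_granularity <= 0) stop("patch_granularity must be > 0")
  structure(list(slough_fraction = slough_fraction,
                 necrosis_fraction = necrosis_fraction,
                 patch_granularity = patch_granularity,
                 seed = as.integer(seed)),
            class = "tissue_layout")
}

#' Build a wound scene from a phantom specification
#'
#' The scene is held in parametric (piecewise-planar) form rather than as a
#' sampled grid so that the LiDAR renderer can intersect rays with it
#' analytically. Heights are queried with [scene_height()].
#'
#' @param spec A [phantom_spec()].
#' @param layout Optional [tissue_layout()] (required for RGB rendering).
#' @return An object of class `wound_scene`.
#' @export
make_cavity_scene <- function(spec, layout = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(layout)) stopifnot(inherits(layout, "tissue_layout"))
  structure(list(spec = spec, layout = layout), class = "wound_scene")
}

# Signed inward distance from the aperture boundary at in-plane coordinates
# (u, v) relative to the wound center; > 0 inside the opening. For the
# elliptical shape the inset is measured radially and scaled by the mean
# semi-axis, which is exact for circles.
scene_inset <- function(scene, u, v) {
  sp <- scene$spec
  du <- u - sp$center_offset[1]
  dv <- v - sp$center_offset[2]
  A <- sp$aperture[1] / 2
  B <- sp$aperture[2] / 2
  if (sp$shape == "rectangular") {
    pmin(A - abs(du), B - abs(dv))
  } else {
    rho <- sqrt((du / A)^2 + (dv / B)^2)
    (A + B) / 2 * (1 - rho)
  }
}

#' Height of the phantom surface relative to the skin plane
#'
#' Returns the surface height in mm at in-plane coordinates `(u, v)`,
#' positive toward the camera: 0 on intact skin, negative inside a cavity
#' (down to `-true_depth` on the floor), positive on a hypergranulation
#' bump.
#'
#' @param scene A `wound_scene`.
#' @param u,v In-plane coordinates in mm (vectorized).
#' @return Numeric vector of heights, mm.
#' @export
scene_height <- function(scene, u, v) {
  sp <- scene$spec
  inset <- scene_inset(scene, u, v)
  k <- tan(sp$edge_angle_deg * pi / 180)
  d <- abs(sp$true_depth)
  sgn <- if (sp$true_depth >= 0) -1 else 1
  g <- numeric(length(inset))
  inside <- inset > 0
  if (any(inside)) {
    ramp <- if (is.finite(k)) pmin(d, k * inset[inside]) else rep(d, sum(inside))
    g[inside] <- ramp
  }
  sgn * g
}

#' @export
print.wound_scene <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "<wound_scene> %s aperture %.3g x %.3g mm, depth %.3g mm, edge %.3g deg, skin at %.3g mm (tilt %.3g deg)\n",
    sp$shape, sp$aperture[1], sp$aperture[2], sp$true_depth,
    sp$edge_angle_deg, sp$skin_distance, sp$skin_tilt_deg))
  if (!is.null(x$layout))
    cat(sprintf("  tissue: slough %.2f, necrosis %.2f, granularity %.3g px\n",
                x$layout$slough_fraction, x$layout$necrosis_fraction,
                x$layout$patch_granularity))
  invisible(x)
}
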