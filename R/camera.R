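#' Pinhole camera model for a time-of-flight depth sensor
#'
#' Describes the intrinsic geometry of the ranging sensor: a pinhole at the
#' origin looking along +z, with x increasing along image columns and y along
#' image rows. Pixel coordinates are 0-based and a pixel's sample point is its
#' center, so the ray through pixel `(r, c)` has direction
#' `((c - cx)/f, (r - cy)/f, 1)`.
#'
#' The default sensor mimics a 192 x 256 mobile LiDAR depth map with a focal
#' length of 210 px (about 60 degrees horizontal field of view); such sensors
#' need roughly 300 mm or more of standoff for reliable ranging, which is what
#' `distance_hint` records.
#'
#' @param focal_length_px Focal length in pixels (> 0).
#' @param image_size Integer vector `(rows, cols)`, both >= 2.
#' @param principal_point Optical center `(row, col)` in 0-based pixel
#'   coordinates; defaults to the image center.
#' @param distance_hint Optional camera-to-scene distance in mm (metadata).
#' @param view_tilt_deg Optional angle between the optical axis and the scene
#'   normal in degrees (metadata).
#' @return An object of class `camera_model`.
#' @export
#' @examples
#' cam <- camera_model()
#' cam$focal_length_px
camera_model <- function(focal_length_px = 210,
                         image_size = c(192L, 256L),
                         principal_point = NULL,
                         distance_hint = NA_real_,
                         view_tilt_deg = NA_real_) {
  stopifnot(is.numeric(focal_length_px), length(focal_length_px) == 1)
  if (focal_length_px <= 0) stop("focal_length_px must be > 0")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 2))
    stop("image_size must be (rows, cols) with both components >= 2")
  if (is.null(principal_point))
    principal_point <- (image_size - 1) / 2
  if (length(principal_point) != 2 ||
      any(principal_point < 0) ||
      principal_point[1] > image_size[1] - 1 ||
      principal_point[2] > image_size[2] - 1)
    stop("principal_point must lie inside the image bounds")
  structure(list(focal_length_px = as.numeric(focal_length_px),
                 principal_point = as.numeric(principal_point),
                 image_size = image_size,
                 distance_hint = distance_hint,
                 view_tilt_deg = view_tilt_deg),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d x %d px, f = %.4g px, pp = (%.4g, %.4g)\n",
              x$image_size[1], x$image_size[2], x$focal_length_px,
              x$principal_point[1], x$principal_point[2]))
  invisible(x)
}

#' Depth map container
#'
#' A matrix of per-pixel range values in millimeters measured along each
#' pixel's ray (what a time-of-flight sensor reports), with `NA` as the
#' missing-value ("no return") sentinel. The native sensor grid is
#' 192 x 256.
#'
#' @param values Numeric matrix of ranges in mm; `NA` marks missing returns.
#' @param cam Optional [camera_model()] attached to the map; its `image_size`
#'   must match `dim(values)`.
#' @param measurement Either `"range"` (distance along the pixel ray, the
#'   sensor-native convention and the default) or `"z"` (distance along the
#'   optical axis).
#' @return `values` with class `depth_map` and the camera attached as an
#'   attribute.
#' @export
depth_map <- function(values, cam = NULL, measurement = c("range", "z")) {
  measurement <- match.arg(measurement)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(values[!is.na(values)] <= 0))
    stop("all non-missing depth values must be > 0 mm")
  if (!is.null(cam)) {
    stopifnot(inherits(cam, "camera_model"))
    if (!all(dim(values) == cam$image_size))
      stop("depth map shape does not match the attached camera_model")
  }
  structure(values, class = c("depth_map", class(values)),
            camera = cam, measurement = measurement, units = "mm")
}

dm_camera <- function(depth, cam = NULL) {
  cam <- cam %||% attr(depth, "camera")
  if (is.null(cam)) stop("no camera_model supplied or attached to the depth map")
  if (!all(dim(depth) == cam$image_size))
    stop("depth map shape does not match the camera_model")
  cam
}

#' @export
print.depth_map <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf("<depth_map> %d x %d px (%s, mm), %d missing, range [%.2f, %.2f]\n",
              nrow(x), ncol(x), attr(x, "measurement"), sum(is.na(x)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}
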