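#' Back-project a depth map to metric 3-D points
#'
#' Converts per-pixel sensor measurements to 3-D points in the camera frame
#' (mm): +z along the optical axis into the scene, x along columns, y along
#' rows. When the map stores range along the ray (the sensor-native
#' convention) the range is first divided by the ray-direction norm to obtain
#' z; when it stores z directly, `x = (c - cx) z / f` and `y = (r - cy) z / f`
#' by similar triangles. Missing pixels yield no point.
#'
#' @param depth A [depth_map()] (or plain matrix, mm).
#' @param cam A [camera_model()]; may be omitted if attached to `depth`.
#' @return A matrix with one row per non-missing pixel and columns
#'   `row`, `col` (0-based pixel coordinates), `x`, `y`, `z` (mm).
#' @export
backproject <- function(depth, cam = NULL) {
  cam <- dm_camera(depth, cam)
  measurement <- attr(depth, "measurement") %||% "range"
  if (all(is.na(depth))) stop("depth map has no valid returns")
  idx <- which(!is.na(depth))
  r <- (idx - 1) %% nrow(depth)       # 0-based
  c <- (idx - 1) %/% nrow(depth)
  f <- cam$focal_length_px
  dx <- (c - cam$principal_point[2]) / f
  dy <- (r - cam$principal_point[1]) / f
  v <- as.numeric(depth[idx])
  z <- if (measurement == "range") v / sqrt(1 + dx^2 + dy^2) else v
  cbind(row = r, col = c, x = dx * z, y = dy * z, z = z)
}

#' Project camera-frame points to pixel coordinates
#'
#' Inverse of [backproject()]: `col = f x / z + cx`, `row = f y / z + cy`
#' (0-based, fractional).
#'
#' @param points Matrix with columns `x`, `y`, `z` (mm), or the output of
#'   [backproject()].
#' @param cam A [camera_model()].
#' @return Matrix with columns `row`, `col`.
#' @export
project_points <- function(points, cam) {
  stopifnot(inherits(cam, "camera_model"))
  pts <- as_points3(points)
  if (any(pts[, 3] <= 0)) stop("points must have z > 0 to project")
  f <- cam$focal_length_px
  cbind(row = f * pts[, 2] / pts[, 3] + cam$principal_point[1],
        col = f * pts[, 1] / pts[, 3] + cam$principal_point[2])
}

as_points3 <- function(points) {
  points <- as.matrix(points)
  cn <- colnames(points)
  if (!is.null(cn) && all(c("x", "y", "z") %in% cn))
    points <- points[, c("x", "y", "z"), drop = FALSE]
  if (ncol(points) != 3) stop("expected points with columns x, y, z")
  storage.mode(points) <- "double"
  points
}

#' Physical footprint of one pixel at a given depth
#'
#' Area on a fronto-parallel plane at depth `z` that maps onto a single
#' pixel: `(z / f)^2` square millimeters. Quadratic in `z`, which is why
#' per-pixel summation of footprints makes metric areas independent of the
#' capture distance.
#'
#' @param z Depth(s) along the optical axis in mm (> 0).
#' @param cam A [camera_model()].
#' @return Footprint(s) in mm^2.
#' @export
#' @examples
#' pixel_footprint(300, camera_model(focal_length_px = 250)) # 1.44 mm^2
pixel_footprint <- function(z, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(!is.finite(z)) || any(z <= 0)) stop("z must be finite and > 0")
  (z / cam$focal_length_px)^2
}

#' Fit a plane to 3-D points by total least squares
#'
#' Orthogonal regression through the centroid: the plane normal is the
#' eigenvector of the point covariance with the smallest eigenvalue, which
#' minimizes the sum of squared orthogonal residuals and is symmetric in all
#' three axes. The normal is oriented away from the camera (positive z
#' component) so that, for a reference skin plane, positive signed distances
#' point down into a wound.
#'
#' @param points Matrix of 3-D points (mm): columns `x`, `y`, `z`, or the
#'   output of [backproject()].
#' @return An object of class `wound_plane`: `normal` (unit 3-vector),
#'   `offset` (mm; the plane is `normal . p = offset`), `rms_residual` (mm)
#'   and `n_support_points`.
#' @export
fit_plane <- function(points) {
  pts <- as_points3(points)
  n <- nrow(pts)
  if (n < 3) stop("degenerate geometry: need at least 3 points to fit a plane")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  e <- eigen(crossprod(x) / n, symmetric = TRUE)
  # collinear (or coincident) points: the two smallest eigenvalues vanish
  scale2 <- max(e$values[1], .Machine$double.eps)
  if (e$values[2] / scale2 < 1e-12)
    stop("degenerate geometry: points are collinear")
  nrm <- e$vectors[, 3]
  if (nrm[3] < 0 || (nrm[3] == 0 && sum(nrm * ctr) < 0)) nrm <- -nrm
  nrm <- nrm / sqrt(sum(nrm^2))
  res <- x %*% nrm
  structure(list(normal = as.numeric(nrm),
                 offset = as.numeric(sum(nrm * ctr)),
                 rms_residual = sqrt(mean(res^2)),
                 n_support_points = n),
            class = "wound_plane")
}

#' @export
print.wound_plane <- function(x, ...) {
  cat(sprintf(
    "<wound_plane> n = (%.4f, %.4f, %.4f), offset = %.3f mm, rms = %.4g mm (%d pts)\n",
    x$normal[1], x$normal[2], x$normal[3], x$offset, x$rms_residual,
    x$n_support_points))
  invisible(x)
}

#' Signed orthogonal distance from a plane
#'
#' Positive values lie on the far side of the plane from the camera
#' (deeper into the scene) given the orientation chosen by [fit_plane()].
#'
#' @param plane A `wound_plane`.
#' @param points 3-D points (see [fit_plane()]).
#' @return Numeric vector of signed distances in mm.
#' @export
plane_distance <- function(plane, points) {
  stopifnot(inherits(plane, "wound_plane"))
  pts <- as_points3(points)
  as.numeric(pts %*% plane$normal) - plane$offset
}

#' Tilt of a plane relative to the optical axis
#'
#' Angle in degrees between the plane normal and the +z axis (0 for a
#' fronto-parallel plane).
#'
#' @param plane A `wound_plane`.
#' @return Angle in degrees.
#' @export
plane_tilt_deg <- function(plane) {
  stopifnot(inherits(plane, "wound_plane"))
  acos(min(1, abs(plane$normal[3]))) * 180 / pi
}

#' Upsample a depth map by bilinear interpolation
#'
#' Smoothly morphs a sensor-resolution map (192 x 256) to a larger grid such
#' as 512 x 683. Corner pixels of source and target are aligned; interpolated
#' values never leave the `[min, max]` of the source, and any target pixel
#' whose bilinear support includes a missing source pixel is itself missing.
#' Upsampling adds no information; it is presentation-level smoothing.
#'
#' @param depth A [depth_map()] or numeric matrix.
#' @param target_size Integer `(rows, cols)`, both at least as large as the
#'   source.
#' @return A `depth_map` of the requested size (camera attribute dropped,
#'   since the intrinsics no longer apply).
#' @export
upsample_depth <- function(depth, target_size) {
  target_size <- as.integer(target_size)
  if (length(target_size) != 2) stop("target_size must be (rows, cols)")
  R <- nrow(depth); C <- ncol(depth)
  if (target_size[1] < R || target_size[2] < C)
    stop("target size must be at least the source size in both axes")
  sr <- if (target_size[1] == 1) rep(0, 1) else
    (seq_len(target_size[1]) - 1) * (R - 1) / (target_size[1] - 1)
  sc <- if (target_size[2] == 1) rep(0, 1) else
    (seq_len(target_size[2]) - 1) * (C - 1) / (target_size[2] - 1)
  r0 <- pmin(floor(sr), R - 2); fr <- sr - r0
  c0 <- pmin(floor(sc), C - 2); fc <- sc - c0
  v <- unclass(depth)
  a00 <- v[cbind(rep(r0 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  a10 <- v[cbind(rep(r0 + 2, length(c0)), rep(c0 + 1, each = length(r0)))]
  a01 <- v[cbind(rep(r0 + 1, length(c0)), rep(c0 + 2, each = length(r0)))]
  a11 <- v[cbind(rep(r0 + 2, length(c0)), rep(c0 + 2, each = length(r0)))]
  wr <- rep(fr, length(c0)); wc <- rep(fc, each = length(r0))
  out <- (1 - wr) * (1 - wc) * a00 + wr * (1 - wc) * a10 +
    (1 - wr) * wc * a01 + wr * wc * a11
  # missing propagates from any supporting source pixel with nonzero weight
  na <- (is.na(a00) & (1 - wr) * (1 - wc) > 0) |
    (is.na(a10) & wr * (1 - wc) > 0) |
    (is.na(a01) & (1 - wr) * wc > 0) |
    (is.na(a11) & wr * wc > 0)
  out[na] <- NA_real_
  m <- matrix(out, nrow = target_size[1], ncol = target_size[2])
  depth_map(m, cam = NULL,
            measurement = attr(depth, "measurement") %||% "range")
}
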