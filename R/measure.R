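# Wound surface area and depth from a depth map plus wound mask: per-pixel
# metric footprint summation with an optional view-angle correction, and
# depth against a total-least-squares plane fitted to the healthy-skin
# boundary ring around the wound.

as_mask <- function(mask, depth = NULL) {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical (or 0/1) matrix")
  if (!is.null(depth) && !all(dim(mask) == dim(depth)))
    stop("mask is not aligned to the depth map")
  mask
}

# z coordinate (along the optical axis) for every pixel of a depth map
pixel_z <- function(depth, cam) {
  measurement <- attr(depth, "measurement") %||% "range"
  if (measurement == "z") return(unclass(depth))
  H <- nrow(depth); W <- ncol(depth)
  dx <- (rep(seq_len(W) - 1, each = H) - cam$principal_point[2]) /
    cam$focal_length_px
  dy <- (rep(seq_len(H) - 1, W) - cam$principal_point[1]) /
    cam$focal_length_px
  matrix(as.numeric(depth) / sqrt(1 + dx^2 + dy^2), H, W)
}

#' Wound surface area from a depth map and wound mask
#'
#' Sums the per-pixel metric footprint `(z/f)^2` over the wound mask. With
#' `angle_adjust = TRUE` (the default) the surrounding-skin reference plane is
#' fitted and the summed (projected) area is divided by the cosine of its
#' tilt, undoing the foreshortening of an obliquely viewed wound.
#'
#' @param mask Logical (or 0/1) wound mask aligned to `depth`.
#' @param depth A [depth_map()] in mm.
#' @param cam A [camera_model()]; may be attached to `depth`.
#' @param angle_adjust Apply the view-angle (cosine) correction.
#' @param ring_width_px Boundary ring width used to fit the skin plane when
#'   adjusting for angle.
#' @return An object of class `area_result`: `area_cm2`, `n_pixels`,
#'   `mean_footprint_mm2`, `tilt_correction_applied`, `tilt_deg`.
#' @export
compute_wound_area <- function(mask, depth, cam = NULL, angle_adjust = TRUE,
                               ring_width_px = 5) {
  cam <- dm_camera(depth, cam)
  mask <- as_mask(mask, depth)
  n_mask <- sum(mask)
  if (n_mask == 0)
    return(structure(list(area_cm2 = 0, n_pixels = 0L,
                          mean_footprint_mm2 = NA_real_,
                          tilt_correction_applied = FALSE,
                          tilt_deg = NA_real_),
                     class = "area_result"))
  miss <- is.na(depth[mask])
  if (mean(miss) >= 0.20)
    stop(sprintf("%.0f%% of wound pixels have missing depth (>= 20%%)",
                 100 * mean(miss)))
  z <- pixel_z(depth, cam)[mask]
  fp <- pixel_footprint(z[!is.na(z)], cam)
  area_mm2 <- sum(fp) * n_mask / sum(!is.na(z))  # scale up for missing pixels
  tilt <- NA_real_
  applied <- FALSE
  if (angle_adjust) {
    plane <- reconstruct_reference_surface(mask, depth, cam, ring_width_px)
    tilt <- plane_tilt_deg(plane)
    area_mm2 <- area_mm2 / cos(tilt * pi / 180)
    applied <- TRUE
  }
  structure(list(area_cm2 = area_mm2 / 100, n_pixels = as.integer(n_mask),
                 mean_footprint_mm2 = mean(fp),
                 tilt_correction_applied = applied, tilt_deg = tilt),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("<area_result> %.3f cm^2 over %d px%s\n", x$area_cm2,
              x$n_pixels,
              if (isTRUE(x$tilt_correction_applied))
                sprintf(", tilt-adjusted (%.2f deg)", x$tilt_deg) else ""))
  invisible(x)
}

#' Reconstruct the healthy-skin reference surface
#'
#' Fits a plane to the boundary ring of healthy skin around the wound (the
#' mask dilated by `ring_width_px` minus the mask itself), representing the
#' estimated level of intact skin prior to injury. The ring must contain at
#' least 30 valid depth pixels; a mask running into the image border can
#' leave too few and raises a degenerate-boundary error.
#'
#' @inheritParams compute_wound_area
#' @param ring_width_px Ring width in (sensor) pixels.
#' @return A `wound_plane` (see [fit_plane()]).
#' @export
reconstruct_reference_surface <- function(mask, depth, cam = NULL,
                                          ring_width_px = 5) {
  cam <- dm_camera(depth, cam)
  mask <- as_mask(mask, depth)
  if (!any(mask)) stop("degenerate boundary: empty wound mask")
  brush <- EBImage::makeBrush(2 * ring_width_px + 1, shape = "box")
  dil <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  ring <- dil & !mask & !is.na(unclass(depth))
  if (sum(ring) < 30)
    stop(sprintf(
      "degenerate boundary: only %d valid ring pixels (need >= 30)",
      sum(ring)))
  masked <- unclass(depth)
  masked[!ring] <- NA_real_
  pts <- backproject(depth_map(masked, cam = cam,
                               measurement = attr(depth, "measurement") %||%
                                 "range"), cam)
  fit_plane(pts)
}

# 3x3 NA-aware box mean, restricted to the mask
smooth3_masked <- function(M, mask) {
  H <- nrow(M); W <- ncol(M)
  acc <- matrix(0, H, W); wt <- matrix(0, H, W)
  V <- ifelse(is.na(M), 0, M)
  ok <- (!is.na(M)) * 1
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    rt <- rs - dr; ct <- cs - dc
    acc[rt, ct] <- acc[rt, ct] + V[rs, cs]
    wt[rt, ct] <- wt[rt, ct] + ok[rs, cs]
  }
  out <- acc / wt
  out[wt == 0 | !mask] <- NA_real_
  out
}

#' Estimate wound depth against the reconstructed skin surface
#'
#' Back-projects the wound pixels, computes each point's signed distance
#' along the reference-plane normal (positive = below skin), smooths the
#' distance image with a 3 x 3 mean to suppress single-pixel noise, and
#' reports the extremum of largest magnitude: the maximum depression, or the
#' maximum elevation as a negative depth when a hypergranulation bump
#' dominates (ties go to depression). Magnitudes below the sensor's
#' resolution floor (3 mm) are reported as the sentinel: `depth_mm = 0`
#' with `sentinel = TRUE`, rendered as `"+/-3"` in reports.
#'
#' @inheritParams reconstruct_reference_surface
#' @param sentinel_mm Resolution floor in mm.
#' @return An object of class `depth_result`: `depth_mm` (signed),
#'   `sentinel`, `extremum_mm` (the underlying signed extremum),
#'   `deepest_pixel` (0-based `(row, col)`), `reference_plane`.
#' @export
estimate_wound_depth <- function(mask, depth, cam = NULL, ring_width_px = 5,
                                 sentinel_mm = 3) {
  cam <- dm_camera(depth, cam)
  mask <- as_mask(mask, depth)
  plane <- reconstruct_reference_surface(mask, depth, cam, ring_width_px)
  masked <- unclass(depth)
  masked[!mask] <- NA_real_
  pts <- backproject(depth_map(masked, cam = cam,
                               measurement = attr(depth, "measurement") %||%
                                 "range"), cam)
  S <- matrix(NA_real_, nrow(depth), ncol(depth))
  S[cbind(pts[, "row"] + 1, pts[, "col"] + 1)] <- plane_distance(plane, pts)
  Ssm <- smooth3_masked(S, mask)
  if (all(is.na(Ssm))) stop("no valid wound depth samples")
  dmax <- max(Ssm, na.rm = TRUE)   # deepest depression
  dmin <- min(Ssm, na.rm = TRUE)   # highest elevation (negative)
  extremum <- if (abs(dmax) >= abs(dmin)) dmax else dmin
  idx <- if (abs(dmax) >= abs(dmin)) which.max(Ssm) else which.min(Ssm)
  rc <- c((idx - 1) %% nrow(S), (idx - 1) %/% nrow(S))
  sentinel <- abs(extremum) < sentinel_mm
  structure(list(depth_mm = if (sentinel) 0 else extremum,
                 sentinel = sentinel,
                 extremum_mm = extremum,
                 deepest_pixel = as.integer(rc),
                 reference_plane = plane),
            class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  if (x$sentinel) cat("<depth_result> +/-3 mm (below resolution floor)\n")
  else cat(sprintf("<depth_result> %.2f mm at pixel (%d, %d)\n", x$depth_mm,
                   x$deepest_pixel[1], x$deepest_pixel[2]))
  invisible(x)
}

#' Format a depth result the way clinical reports print it
#'
#' @param x A `depth_result`.
#' @return `"+/-3"` for sentinel results, otherwise the depth in mm.
#' @export
format_depth <- function(x) {
  stopifnot(inherits(x, "depth_result"))
  if (x$sentinel) "+/-3" else format(round(x$depth_mm, 2))
}

#' End-to-end measurement of one capture
#'
#' Runs the full single-image pipeline: wound segmentation (or a supplied
#' ground-truth mask), surface area, depth against the reconstructed skin
#' plane, and tissue composition when an RGB image and a stage-2 model (or
#' ground-truth tissue map) are available.
#'
#' @param depth A [depth_map()].
#' @param cam A [camera_model()].
#' @param rgb Optional RGB array (H x W x 3, values in [0,1]) for tissue
#'   analysis.
#' @param mask Optional ground-truth wound mask; if `NULL`, `models$stage1`
#'   segments the wound from `rgb`.
#' @param models Optional list with `stage1` and `stage2` [build_unet()]
#'   models.
#' @param tissue Optional ground-truth tissue map (used when no stage-2 model
#'   is given).
#' @param angle_adjust Apply the view-angle area correction.
#' @return An object of class `wound_report` (serialize with
#'   [write_report()]).
#' @export
measure <- function(depth, cam = NULL, rgb = NULL, mask = NULL,
                    models = NULL, tissue = NULL, angle_adjust = TRUE) {
  cam <- dm_camera(depth, cam)
  mask_source <- "ground-truth"
  if (is.null(mask)) {
    if (is.null(models$stage1) || is.null(rgb))
      stop("either a mask or (rgb + models$stage1) is required")
    mask <- segment_wound(models$stage1, rgb)
    mask_source <- "unet-stage1"
  }
  mask <- as_mask(mask, depth)
  area <- tryCatch(compute_wound_area(mask, depth, cam, angle_adjust),
                   error = function(e) stop("area stage: ",
                                            conditionMessage(e)))
  depth_res <- tryCatch(estimate_wound_depth(mask, depth, cam),
                        error = function(e) stop("depth stage: ",
                                                 conditionMessage(e)))
  tf <- NULL
  tissue_source <- NULL
  if (!is.null(models$stage2) && !is.null(rgb)) {
    tm <- segment_tissue(models$stage2, rgb, mask)
    tf <- tissue_fractions(tm, mask)
    tissue_source <- "unet-stage2"
  } else if (!is.null(tissue)) {
    tf <- tissue_fractions(tissue, mask)
    tissue_source <- "ground-truth"
  }
  structure(list(area = area, depth = depth_res, tissue_fractions = tf,
                 provenance = list(mask_source = mask_source,
                                   tissue_source = tissue_source,
                                   angle_adjust = angle_adjust)),
            class = "wound_report")
}

#' @export
print.wound_report <- function(x, ...) {
  cat("<wound_report>\n")
  cat(sprintf("  area:  %.3f cm^2\n", x$area$area_cm2))
  cat(sprintf("  depth: %s mm\n", format_depth(x$depth)))
  if (!is.null(x$tissue_fractions))
    cat(sprintf("  tissue: slough %.2f%%, necrosis %.2f%%\n",
                x$tissue_fractions$slough_pct,
                x$tissue_fractions$necrosis_pct))
  invisible(x)
}
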