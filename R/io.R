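# File formats: 8-bit PNG for RGB images, small-palette grayscale PNG for
# masks and tissue maps (level = class index), 16-bit grayscale PNG plus a
# JSON sidecar for depth maps (default quantization 0.1 mm/unit, well under
# the 3 mm resolution floor), and deterministic JSON reports (sorted keys,
# fixed float format) so reruns are byte-identical.

#' Read an RGB image or grayscale map from PNG
#'
#' 16-bit inputs are down-converted to the [0,1] double scale with a warning.
#'
#' @param path PNG file.
#' @return H x W x 3 array (or matrix for grayscale), values in [0,1].
#' @export
read_image <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth > 8)
    warning(sprintf("%d-bit image down-converted to 8-bit working range",
                    info$bit.depth))
  if (length(dim(img)) == 3 && dim(img)[3] == 4)
    img <- img[, , 1:3]  # drop alpha
  attr(img, "info") <- NULL
  img
}

#' Write an RGB image (or grayscale matrix) as 8-bit PNG
#'
#' @param img Array in [0,1].
#' @param path Output PNG.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a categorical mask as a palette-style PNG
#'
#' Class indices are stored as 8-bit gray levels (0 = background/other,
#' 1 = wound or slough, 2 = necrosis), which round-trips losslessly.
#'
#' @param mask Integer/logical matrix of class indices.
#' @param path Output PNG.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (any(m < 0 | m > 255)) stop("mask indices must be in 0..255")
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read a categorical mask written by [write_mask()]
#'
#' @param path PNG file.
#' @param max_index Largest legal class index; higher values raise a format
#'   error.
#' @return Integer matrix of class indices.
#' @export
read_mask <- function(path, max_index = 2L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  if (any(m > max_index))
    stop(sprintf("format error: palette index %d exceeds max index %d",
                 max(m), max_index))
  m
}

#' Write a depth map as 16-bit PNG with a JSON sidecar
#'
#' Values are quantized to `scale_mm_per_unit` (default 0.1 mm); missing
#' pixels are stored as the reserved `missing_value` code. The sidecar
#' (`<path>.json`) records the scale, the missing code and the camera
#' intrinsics needed to interpret the map.
#'
#' @param depth A [depth_map()].
#' @param path Output PNG path.
#' @param cam A [camera_model()] (or attached to `depth`).
#' @param scale_mm_per_unit Quantization step in mm per integer unit.
#' @param missing_value Reserved 16-bit code for missing returns.
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path, cam = NULL, scale_mm_per_unit = 0.1,
                        missing_value = 65535L) {
  cam <- dm_camera(depth, cam)
  raw <- round(unclass(depth) / scale_mm_per_unit)
  if (any(raw[!is.na(raw)] >= missing_value))
    stop("depth exceeds the 16-bit range at this scale")
  raw[is.na(raw)] <- missing_value
  cpp_write_png16(matrix(as.integer(raw), nrow(raw), ncol(raw)), path)
  sidecar <- list(scale_mm_per_unit = scale_mm_per_unit,
                  missing_value = as.integer(missing_value),
                  focal_length_px = cam$focal_length_px,
                  principal_point = cam$principal_point,
                  image_size = cam$image_size,
                  measurement = attr(depth, "measurement") %||% "range")
  writeLines(canonical_json(sidecar), paste0(path, ".json"))
  invisible(path)
}

#' Read a depth map written by [write_depth()]
#'
#' @param path PNG path; `<path>.json` must exist.
#' @return A [depth_map()] with the camera attached.
#' @export
read_depth <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("format error: missing depth sidecar ", side_path)
  side <- jsonlite::fromJSON(side_path)
  for (field in c("scale_mm_per_unit", "missing_value", "focal_length_px",
                  "principal_point"))
    if (is.null(side[[field]]))
      stop("format error: sidecar lacks field '", field, "'")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) stop("depth PNG must be single-channel")
  raw <- round(img * 65535)
  vals <- raw * side$scale_mm_per_unit
  vals[raw == side$missing_value] <- NA_real_
  cam <- camera_model(focal_length_px = side$focal_length_px,
                      image_size = side$image_size %||% dim(img),
                      principal_point = side$principal_point)
  depth_map(vals, cam = cam,
            measurement = side$measurement %||% "range")
}

# Deterministic JSON: sorted keys, fixed number formatting (up to 8
# significant digits, integers printed as integers), no locale dependence.
canonical_json <- function(x) {
  fmt <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      nm <- sort(names(v))
      return(paste0("{", paste0(vapply(nm, function(k)
        paste0("\"", k, "\":", fmt(v[[k]])), character(1)), collapse = ","),
        "}"))
    }
    if (is.list(v) || length(v) > 1)
      return(paste0("[", paste0(vapply(as.list(v), fmt, character(1)),
                                collapse = ","), "]"))
    if (length(v) == 0) return("[]")
    if (is.character(v)) return(paste0("\"", gsub("\"", "\\\\\"", v), "\""))
    if (is.logical(v)) return(if (is.na(v)) "null" else
      if (v) "true" else "false")
    if (is.na(v)) return("null")
    if (is.numeric(v)) {
      if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
      return(sprintf("%.8g", v))
    }
    stop("cannot serialize value of class ", class(v)[1])
  }
  fmt(x)
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; used to stamp outputs so a rerun
#' with identical configuration is recognizable.
#'
#' @param x Any serializable list/vector structure.
#' @return Hex digest string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canonical_json(x), tf)
  unname(tools::md5sum(tf))
}

#' Serialize a measurement report as deterministic JSON
#'
#' Keys are sorted and floats printed in a fixed format, so re-running the
#' same measurement produces a byte-identical file. Sentinel depths are
#' rendered as the string `"+/-3"`.
#'
#' @param report A `wound_report` from [measure()], or any list.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @param extra Optional named list merged into the document (e.g. seeds).
#' @return The JSON string, invisibly if written to a file.
#' @export
write_report <- function(report, path = NULL, extra = NULL) {
  doc <- list(schema = "wound-report/1", tool = "woundlidar",
              version = as.character(utils::packageVersion("woundlidar")))
  if (inherits(report, "wound_report")) {
    doc$area <- report$area[c("area_cm2", "n_pixels", "mean_footprint_mm2",
                              "tilt_correction_applied", "tilt_deg")]
    doc$depth <- list(depth = format_depth(report$depth),
                      depth_mm = report$depth$depth_mm,
                      sentinel = report$depth$sentinel,
                      deepest_pixel = report$depth$deepest_pixel,
                      plane_rms_mm = report$depth$reference_plane$rms_residual)
    if (!is.null(report$tissue_fractions))
      doc$tissue <- report$tissue_fractions[c("slough_pct", "necrosis_pct",
                                              "wound_pixels")]
    doc$provenance <- report$provenance
  } else {
    doc <- c(doc, report)
  }
  if (!is.null(extra)) doc <- c(doc, extra)
  doc$config_hash <- config_hash(doc)
  out <- canonical_json(doc)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Write a scene bundle to a directory
#'
#' Produces `rgb.png`, `depth.png` (+ `.json` sidecar), `wound_mask.png`,
#' `tissue.png` and `spec.json`.
#'
#' @param scene A `wound_scene` (with a tissue layout).
#' @param dir Output directory (created if needed).
#' @param cam A [camera_model()].
#' @param seed Render seed (defaults to the spec's).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(scene, dir, cam = camera_model(),
                               seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- seed %||% scene$spec$seed
  rr <- render_rgb(scene, cam, seed = seed)
  dm <- render_lidar(scene, cam, seed = seed)
  write_image(rr$rgb, file.path(dir, "rgb.png"))
  write_depth(dm, file.path(dir, "depth.png"), cam)
  write_mask(rr$wound_mask * 1L, file.path(dir, "wound_mask.png"))
  write_mask(rr$tissue_map, file.path(dir, "tissue.png"))
  spec_doc <- list(spec = unclass(scene$spec),
                   layout = if (!is.null(scene$layout))
                     unclass(scene$layout))
  writeLines(canonical_json(spec_doc), file.path(dir, "spec.json"))
  invisible(dir)
}

#' Write a generated dataset to a directory
#'
#' Writes `rgb_NNNN.png`, `mask_NNNN.png`, `tissue_NNNN.png` per image plus
#' `manifest.csv` (paths, split, generating parameters).
#'
#' @param ds A `wound_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "wound_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ds$images)[4]
  man <- ds$manifest
  man$rgb <- sprintf("rgb_%04d.png", seq_len(n))
  man$mask <- sprintf("mask_%04d.png", seq_len(n))
  man$tissue <- sprintf("tissue_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    write_image(ds$images[, , , i], file.path(dir, man$rgb[i]))
    write_mask(ds$masks[, , i], file.path(dir, man$mask[i]))
    write_mask(ds$tissues[, , i], file.path(dir, man$tissue[i]))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the PNG files.
#' @return A `wound_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  n <- nrow(man)
  first <- read_image(file.path(dir, man$rgb[1]))
  H <- dim(first)[1]; W <- dim(first)[2]
  images <- array(0, dim = c(H, W, 3, n))
  masks <- array(0L, dim = c(H, W, n))
  tissues <- array(0L, dim = c(H, W, n))
  for (i in seq_len(n)) {
    images[, , , i] <- read_image(file.path(dir, man$rgb[i]))
    masks[, , i] <- read_mask(file.path(dir, man$mask[i]), 1L)
    tissues[, , i] <- read_mask(file.path(dir, man$tissue[i]), 2L)
  }
  structure(list(images = images, masks = masks, tissues = tissues,
                 manifest = man,
                 camera = camera_model(focal_length_px = 200,
                                       image_size = c(H, W))),
            class = "wound_dataset")
}
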