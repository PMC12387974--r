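# Analytic ray casting against the piecewise-planar phantom primitives
# (skin plane, floor/top plane, sloped walls). Each candidate intersection is
# validated by checking that the hit point actually lies on the surface
# (|w - height(u,v)| < 1e-6 mm), so region bookkeeping never drifts from the
# height-field definition; vertical walls (edge angle 90) are the one case
# validated by their own band test because the height field is discontinuous
# there.

ray_cast <- function(scene, cam) {
  sp <- scene$spec
  H <- cam$image_size[1]; W <- cam$image_size[2]
  f <- cam$focal_length_px
  th <- sp$skin_tilt_deg * pi / 180
  D <- sp$skin_distance
  w0 <- D * cos(th)
  wf <- -sp$true_depth                      # floor (or bump top) height
  if (w0 <= max(0, wf)) stop("camera lies inside the scene geometry")
  k <- tan(sp$edge_angle_deg * pi / 180)
  vertical <- !is.finite(k) || sp$edge_angle_deg >= 90
  sgn <- if (sp$true_depth >= 0) 1 else -1  # wall height = -sgn * k * inset
  d <- abs(sp$true_depth)
  u0 <- sp$center_offset[1]; v0 <- sp$center_offset[2]
  A <- sp$aperture[1] / 2; B <- sp$aperture[2] / 2

  r <- rep(seq_len(H) - 1, W)
  cc <- rep(seq_len(W) - 1, each = H)
  dx <- (cc - cam$principal_point[2]) / f
  dy <- (r - cam$principal_point[1]) / f
  dn <- sqrt(1 + dx^2 + dy^2)
  bu <- dx
  bv <- dy * cos(th) + sin(th)
  bw <- dy * sin(th) - cos(th)
  av <- -D * sin(th)                        # v(t) = av + bv*t ; u(t) = bu*t

  uu <- function(t) bu * t
  vv <- function(t) av + bv * t
  ww <- function(t) w0 + bw * t

  check <- function(t) {
    ok <- is.finite(t) & t > 1e-9
    t[!ok] <- Inf
    i <- which(is.finite(t))
    if (length(i)) {
      h <- scene_height(scene, bu[i] * t[i], av + bv[i] * t[i])
      bad <- abs(w0 + bw[i] * t[i] - h) > 1e-6
      t[i][bad] <- Inf
    }
    t
  }
  lin_t <- function(num, den) {
    t <- num / den
    t[abs(den) < 1e-12] <- Inf
    t
  }
  cand <- list()
  # intact skin plane: w = 0
  cand$skin <- check(lin_t(-w0, bw))
  if (d > 0) {
    # floor / bump-top plane: w = wf
    cand$floor <- check(lin_t(wf - w0, bw))
    if (vertical) {
      band <- function(t, inside_other) {
        w <- ww(t)
        ok <- is.finite(t) & t > 1e-9 & inside_other &
          w >= min(0, wf) - 1e-9 & w <= max(0, wf) + 1e-9
        t[!ok] <- Inf
        t
      }
      if (sp$shape == "rectangular") {
        for (s in c(1, -1)) {
          tU <- lin_t(s * A + u0, bu)
          cand[[paste0("wu", s)]] <- band(tU, abs(vv(tU) - v0) <= B + 1e-9)
          tV <- lin_t(s * B + v0 - av, bv)
          cand[[paste0("wv", s)]] <- band(tV, abs(uu(tV) - u0) <= A + 1e-9)
        }
      } else {
        aau <- -u0; aav <- av - v0
        qa <- (bu / A)^2 + (bv / B)^2
        qb <- 2 * (aau * bu / A^2 + aav * bv / B^2)
        qc <- (aau / A)^2 + (aav / B)^2 - 1
        disc <- qb^2 - 4 * qa * qc
        sq <- sqrt(pmax(disc, 0))
        for (s in c(1, -1)) {
          t <- (-qb + s * sq) / (2 * qa)
          t[disc < 0] <- Inf
          cand[[paste0("we", s)]] <- band(t, TRUE)
        }
      }
    } else if (sp$shape == "rectangular") {
      ke <- sgn * k
      cand$wall_pu <- check(lin_t(-ke * (A + u0) - w0, bw - ke * bu))
      cand$wall_mu <- check(lin_t(-ke * (A - u0) - w0, bw + ke * bu))
      cand$wall_pv <- check(lin_t(-ke * (B + v0 - av) - w0, bw - ke * bv))
      cand$wall_mv <- check(lin_t(-ke * (B - v0 + av) - w0, bw + ke * bv))
    } else {
      ce <- (A + B) / 2
      p <- 1 + sgn * w0 / (k * ce)
      q <- sgn * bw / (k * ce)
      aau <- -u0; aav <- av - v0
      qa <- (bu / A)^2 + (bv / B)^2 - q^2
      qb <- 2 * (aau * bu / A^2 + aav * bv / B^2 - p * q)
      qc <- (aau / A)^2 + (aav / B)^2 - p^2
      disc <- qb^2 - 4 * qa * qc
      sq <- sqrt(pmax(disc, 0))
      for (s in c(1, -1)) {
        t <- (-qb + s * sq) / (2 * qa)
        t[disc < 0] <- Inf
        cand[[paste0("we", s)]] <- check(t)
      }
    }
  }
  tbest <- Reduce(pmin, cand)
  hit <- is.finite(tbest)
  range <- ifelse(hit, tbest * dn, NA_real_)
  list(range = matrix(range, H, W),
       u = matrix(ifelse(hit, bu * tbest, NA_real_), H, W),
       v = matrix(ifelse(hit, av + bv * tbest, NA_real_), H, W),
       w = matrix(ifelse(hit, w0 + bw * tbest, NA_real_), H, W),
       hit = matrix(hit, H, W))
}

#' Render a LiDAR depth map of a phantom scene
#'
#' Casts one ray per sensor pixel from the pinhole and returns the range to
#' the first surface intersection, in mm, with i.i.d. Gaussian range noise
#' added. Occlusion (wound floor hidden behind steep or overhanging geometry
#' as seen from the pinhole) arises naturally from first-hit selection.
#' Deterministic for a fixed seed.
#'
#' @param scene A `wound_scene` from [make_cavity_scene()].
#' @param cam A [camera_model()]; defaults to the 192 x 256 sensor.
#' @param noise_sd Range noise sd in mm; defaults to the phantom spec value.
#' @param seed Noise seed; defaults to the phantom spec value.
#' @return A [depth_map()] (range along ray, mm) with the camera attached.
#' @export
render_lidar <- function(scene, cam = camera_model(), noise_sd = NULL,
                         seed = NULL) {
  stopifnot(inherits(scene, "wound_scene"))
  noise_sd <- noise_sd %||% scene$spec$noise_sd
  seed <- seed %||% scene$spec$seed
  rc <- ray_cast(scene, cam)
  rng <- rc$range
  if (noise_sd > 0) {
    n <- with_seed(seed, rnorm(length(rng), 0, noise_sd))
    rng <- rng + matrix(n, nrow(rng), ncol(rng))
    rng[rng <= 0.1] <- 0.1
  }
  depth_map(rng, cam = cam, measurement = "range")
}

#' Ground-truth wound mask and tissue map for a scene
#'
#' Renders, through the same camera used for imaging, the per-pixel ground
#' truth: which pixels view the wound opening, and the tissue class (0 other,
#' 1 slough, 2 necrosis) painted by the scene's [tissue_layout()]. Tissue
#' patches come from a seeded smooth lattice noise field over the wound plane,
#' rank-thresholded so the target area fractions are met exactly up to
#' pixelation.
#'
#' @param scene A `wound_scene`.
#' @param cam A [camera_model()].
#' @return List with `wound_mask` (logical matrix) and `tissue_map` (integer
#'   matrix, nonzero only inside the mask), plus the hit coordinates.
#' @export
render_ground_truth <- function(scene, cam = camera_model()) {
  rc <- ray_cast(scene, cam)
  inset <- matrix(scene_inset(scene, as.numeric(rc$u), as.numeric(rc$v)),
                  nrow(rc$u), ncol(rc$u))
  mask <- rc$hit & !is.na(inset) & inset > 0
  tissue <- matrix(0L, nrow(mask), ncol(mask))
  lay <- scene$layout
  if (!is.null(lay) && any(mask) &&
      (lay$slough_fraction > 0 || lay$necrosis_fraction > 0)) {
    fld <- tissue_field(scene, cam, rc$u[mask], rc$v[mask])
    nw <- sum(mask)
    ns <- round(lay$slough_fraction * nw)
    nn <- round(lay$necrosis_fraction * nw)
    rk <- rank(fld, ties.method = "first")
    cls <- integer(nw)
    cls[rk <= ns] <- 1L
    cls[rk > nw - nn] <- 2L
    tissue[mask] <- cls
  }
  list(wound_mask = mask, tissue_map = tissue, u = rc$u, v = rc$v,
       w = rc$w, range = rc$range)
}

# Smooth seeded lattice ("value") noise over the wound plane, bilinear
# between lattice nodes. Lattice spacing is patch_granularity px converted to
# mm at the skin distance.
tissue_field <- function(scene, cam, u, v) {
  lay <- scene$layout
  sp <- scene$spec
  h <- lay$patch_granularity * sp$skin_distance / cam$focal_length_px
  ou <- sp$center_offset[1] - sp$aperture[1] / 2 - 2 * h
  ov <- sp$center_offset[2] - sp$aperture[2] / 2 - 2 * h
  nu <- ceiling((sp$aperture[1] + 4 * h) / h) + 2
  nv <- ceiling((sp$aperture[2] + 4 * h) / h) + 2
  G <- with_seed(lay$seed, matrix(rnorm(nu * nv), nu, nv))
  gu <- pmin(pmax((u - ou) / h, 0), nu - 1 - 1e-9)
  gv <- pmin(pmax((v - ov) / h, 0), nv - 1 - 1e-9)
  i0 <- floor(gu); j0 <- floor(gv)
  fu <- gu - i0; fv <- gv - j0
  g <- function(ii, jj) G[cbind(ii + 1, jj + 1)]
  (1 - fu) * (1 - fv) * g(i0, j0) + fu * (1 - fv) * g(i0 + 1, j0) +
    (1 - fu) * fv * g(i0, j0 + 1) + fu * fv * g(i0 + 1, j0 + 1)
}

# Per-class base colors (RGB in [0,1]) and pixel noise sd for the synthetic
# wound photos; fixed generator constants.
tissue_colors <- function() {
  list(means = rbind(skin = c(0.86, 0.67, 0.52),
                     other = c(0.68, 0.22, 0.22),
                     slough = c(0.84, 0.78, 0.45),
                     necrosis = c(0.18, 0.13, 0.11)),
       sds = c(skin = 0.025, other = 0.03, slough = 0.04, necrosis = 0.02))
}

#' Render a synthetic wound photo with aligned ground truth
#'
#' Generates the RGB surrogate for a clinical wound photograph: beige skin,
#' red granulation, yellow fibrous slough and near-black necrosis, each drawn
#' from a fixed color distribution, modulated by the tissue patch field, a
#' depth-shading cue, a mild lighting gradient, and seeded per-pixel noise.
#' The returned wound mask and tissue map are pixel-aligned with the image.
#'
#' @param scene A `wound_scene` whose layout is set (see [tissue_layout()]).
#' @param cam A [camera_model()].
#' @param seed Pixel-noise seed; defaults to the phantom spec seed.
#' @param skin_only If `TRUE`, render intact skin only (a negative training
#'   example: the wound mask is empty).
#' @return List with `rgb` (H x W x 3 array in [0,1]), `wound_mask` (logical
#'   matrix) and `tissue_map` (integer matrix; 0 other, 1 slough, 2 necrosis).
#' @export
render_rgb <- function(scene, cam = camera_model(), seed = NULL,
                       skin_only = FALSE) {
  stopifnot(inherits(scene, "wound_scene"))
  if (is.null(scene$layout) && !skin_only)
    stop("scene has no tissue_layout; supply one to make_cavity_scene()")
  seed <- seed %||% scene$spec$seed
  H <- cam$image_size[1]; W <- cam$image_size[2]
  if (skin_only) {
    gt <- list(wound_mask = matrix(FALSE, H, W),
               tissue_map = matrix(0L, H, W))
    cls <- matrix(1L, H, W)  # all skin
    depthshade <- matrix(1, H, W)
    fieldn <- matrix(0, H, W)
  } else {
    gt <- render_ground_truth(scene, cam)
    cls <- matrix(1L, H, W)
    cls[gt$wound_mask] <- 2L + gt$tissue_map[gt$wound_mask]  # 2 other,3 slough,4 necrosis
    g <- pmax(0, -gt$w)   # cavity depth at the hit, mm
    depthshade <- 1 - 0.25 * pmin(g / 15, 1)
    depthshade[is.na(depthshade)] <- 1
    fieldn <- matrix(0, H, W)
    if (any(gt$wound_mask)) {
      fl <- tissue_field(scene, cam, gt$u[gt$wound_mask], gt$v[gt$wound_mask])
      fieldn[gt$wound_mask] <- tanh(fl)
    }
  }
  pal <- tissue_colors()
  light <- outer(seq_len(H) - 1, seq_len(W) - 1,
                 function(r, c) 0.92 + 0.12 * c / (W - 1) + 0.04 * r / (H - 1))
  img <- array(0, dim = c(H, W, 3))
  noise <- with_seed(seed, array(rnorm(H * W * 3), dim = c(H, W, 3)))
  streak <- if (!skin_only && any(cls == 3L)) {
    s <- 0.05 * sin(2 * pi * gt$u / 2.5 + 3 * fieldn)
    s[is.na(s)] <- 0
    s
  } else matrix(0, H, W)
  for (ch in 1:3) {
    base <- pal$means[cls, ch]
    sdv <- pal$sds[cls]
    chan <- (base * (1 + 0.10 * as.numeric(fieldn)) +
               as.numeric(noise[, , ch]) * sdv) *
      as.numeric(light) * as.numeric(depthshade)
    if (ch < 3) chan <- chan + as.numeric(streak) * (cls == 3L)
    img[, , ch] <- matrix(pmin(pmax(chan, 0), 1), H, W)
  }
  list(rgb = img, wound_mask = gt$wound_mask, tissue_map = gt$tissue_map)
}

#' Generate a synthetic training corpus of wound photos
#'
#' Samples random phantom specs and tissue layouts, renders each to an RGB
#' image with ground-truth wound mask and tissue map, and partitions the
#' result into disjoint train/validation/test splits (70/20/10 by default,
#' rounded). A fraction of images are intact-skin negatives. Deterministic
#' for a fixed seed.
#'
#' @param n Number of images (>= 10).
#' @param seed Integer seed.
#' @param split Proportions `(train, validation, test)` summing to 1.
#' @param image_size Rendered image size `(rows, cols)` in px.
#' @param p_empty Probability an image is an intact-skin negative.
#' @param dir Optional directory: writes `rgb_NNNN.png`, `mask_NNNN.png`,
#'   `tissue_NNNN.png` and `manifest.csv`.
#' @return An object of class `wound_dataset`: arrays `images`
#'   (H x W x 3 x n), `masks`, `tissues` (H x W x n), the manifest data frame
#'   and the rendering camera.
#' @export
generate_dataset <- function(n, seed = 1L, split = c(0.70, 0.20, 0.10),
                             image_size = c(128L, 128L), p_empty = 0.10,
                             dir = NULL) {
  if (n < 10) stop("n must be >= 10")
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-8)
    stop("split must be three proportions summing to 1")
  cam <- camera_model(focal_length_px = 200, image_size = image_size)
  H <- image_size[1]; W <- image_size[2]
  params <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- if (runif(1) < 0.25) 0 else runif(1, 0.05, 0.70)
      nec <- if (runif(1) < 0.50) 0 else runif(1, 0.05, max(0.05, 0.9 - s) * 0.6)
      list(skin_distance = runif(1, 250, 400),
           aperture = c(runif(1, 25, 80), runif(1, 25, 80)),
           true_depth = runif(1, 0, 20),
           edge_angle_deg = runif(1, 40, 90),
           shape = sample(c("rectangular", "elliptical"), 1),
           skin_tilt_deg = runif(1, 0, 15),
           center_offset = runif(2, -18, 18),
           slough = s, necrosis = min(nec, 1 - s),
           granularity = runif(1, 8, 24),
           empty = runif(1) < p_empty,
           seed_render = sample.int(1e9, 1),
           seed_tissue = sample.int(1e9, 1))
    })
  })
  n_tr <- round(split[1] * n); n_va <- round(split[2] * n)
  n_te <- n - n_tr - n_va
  splits <- rep(c("train", "validation", "test"), c(n_tr, n_va, n_te))
  images <- array(0, dim = c(H, W, 3, n))
  masks <- array(0L, dim = c(H, W, n))
  tissues <- array(0L, dim = c(H, W, n))
  for (i in seq_len(n)) {
    p <- params[[i]]
    sp <- phantom_spec(skin_distance = p$skin_distance, aperture = p$aperture,
                       true_depth = p$true_depth,
                       edge_angle_deg = p$edge_angle_deg, shape = p$shape,
                       skin_tilt_deg = p$skin_tilt_deg,
                       center_offset = p$center_offset,
                       noise_sd = 0, seed = p$seed_render)
    lay <- tissue_layout(p$slough, p$necrosis, p$granularity, p$seed_tissue)
    rr <- render_rgb(make_cavity_scene(sp, lay), cam, seed = p$seed_render,
                     skin_only = p$empty)
    images[, , , i] <- rr$rgb
    masks[, , i] <- rr$wound_mask * 1L
    tissues[, , i] <- rr$tissue_map
  }
  manifest <- data.frame(
    id = seq_len(n), split = splits,
    empty = vapply(params, `[[`, logical(1), "empty"),
    skin_distance = vapply(params, `[[`, numeric(1), "skin_distance"),
    aperture_w = vapply(params, function(p) p$aperture[1], numeric(1)),
    aperture_l = vapply(params, function(p) p$aperture[2], numeric(1)),
    true_depth = vapply(params, `[[`, numeric(1), "true_depth"),
    edge_angle_deg = vapply(params, `[[`, numeric(1), "edge_angle_deg"),
    shape = vapply(params, `[[`, character(1), "shape"),
    skin_tilt_deg = vapply(params, `[[`, numeric(1), "skin_tilt_deg"),
    slough_fraction = vapply(params, `[[`, numeric(1), "slough"),
    necrosis_fraction = vapply(params, `[[`, numeric(1), "necrosis"),
    seed_render = vapply(params, `[[`, numeric(1), "seed_render"),
    stringsAsFactors = FALSE)
  ds <- structure(list(images = images, masks = masks, tissues = tissues,
                       manifest = manifest, camera = cam, seed = seed),
                  class = "wound_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.wound_dataset <- function(x, ...) {
  cat(sprintf("<wound_dataset> %d images %d x %d, splits: %s\n",
              dim(x$images)[4], dim(x$images)[1], dim(x$images)[2],
              paste(sprintf("%s=%d", names(table(x$manifest$split)),
                            table(x$manifest$split)), collapse = ", ")))
  invisible(x)
}

#' Indices of a dataset split
#'
#' @param ds A `wound_dataset`.
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @return Integer indices into the dataset arrays.
#' @export
dataset_split <- function(ds, split = c("train", "validation", "test")) {
  split <- match.arg(split)
  which(ds$manifest$split == split)
}

#' Bench sweep of phantom configurations through the depth pipeline
#'
#' Renders each (depth, aperture, edge-angle) configuration `repeats` times
#' with fresh noise and runs [estimate_wound_depth()] on the ground-truth
#' wound mask, mirroring the bench protocol in which each phantom setting is
#' photographed 8-10 times. When `apertures` is `NULL`, the aperture of each
#' configuration is coupled to its depth so the cavity keeps a
#' `floor_width`-mm flat floor (the bench model narrows the opening as it
#' deepens; an aperture too small for the depth would turn the cavity into a
#' V-groove whose physical depth is less than the nominal setting).
#'
#' @param depths Cavity depths in mm.
#' @param apertures Aperture widths in mm crossed with the other lists, or
#'   `NULL` to couple aperture to depth via `floor_width`.
#' @param edge_angles Wall steepness values in degrees.
#' @param repeats Renders per configuration.
#' @param seed Integer seed.
#' @param noise_sd Range noise sd in mm.
#' @param cam A [camera_model()].
#' @param floor_width Flat floor width in mm used when `apertures` is `NULL`.
#' @return Data frame with one row per rendered image: the configuration,
#'   the true depth, the estimated depth, the sentinel flag and the signed
#'   error in mm.
#' @export
sweep_invitro <- function(depths, apertures = NULL, edge_angles = 90,
                          repeats = 8, seed = 1L, noise_sd = 1,
                          cam = camera_model(), floor_width = 24) {
  if (!length(depths) || !length(edge_angles)) stop("empty sweep lists")
  grid <- if (is.null(apertures)) {
    g <- expand.grid(depth = depths, edge = edge_angles)
    g$aperture <- floor_width + 2 * g$depth / tan(g$edge * pi / 180)
    g
  } else {
    g <- expand.grid(depth = depths, edge = edge_angles, aperture = apertures)
    g
  }
  seeds <- with_seed(seed, sample.int(1e9, nrow(grid) * repeats))
  out <- vector("list", nrow(grid) * repeats)
  row <- 0L
  for (i in seq_len(nrow(grid))) {
    sp <- phantom_spec(aperture = grid$aperture[i],
                       true_depth = grid$depth[i],
                       edge_angle_deg = grid$edge[i],
                       shape = "elliptical", noise_sd = noise_sd)
    scene <- make_cavity_scene(sp)
    gt <- render_ground_truth(scene, cam)
    for (j in seq_len(repeats)) {
      row <- row + 1L
      dm <- render_lidar(scene, cam, noise_sd = noise_sd,
                         seed = seeds[row])
      dr <- estimate_wound_depth(gt$wound_mask, dm, cam)
      out[[row]] <- data.frame(
        config = i, depth = grid$depth[i], aperture = grid$aperture[i],
        edge_angle_deg = grid$edge[i], rep = j,
        est_depth = dr$depth_mm, sentinel = dr$sentinel,
        error = dr$depth_mm - grid$depth[i])
    }
  }
  do.call(rbind, out)
}
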