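#' Configuration for a U-Net segmentation stage
#'
#' Desk-scale defaults: 128 x 128 inputs, 3 pooling levels, 16 base filters
#' (about half a million parameters), pixel-wise cross-entropy plus soft-dice
#' loss, Adam at 1e-3, batches of 8, and early stopping when validation loss
#' fails to improve by more than `min_delta` for `early_stop_patience`
#' consecutive epochs (10 by default).
#'
#' @param classes Character vector of class labels. Stage 1 uses
#'   `c("background", "wound")`; stage 2 uses
#'   `c("other", "slough", "necrosis")`.
#' @param input_size Input image size `(rows, cols)`; must be divisible by
#'   `2^depth_levels`.
#' @param depth_levels Number of pooling stages (>= 2).
#' @param base_filters Filters in the first encoder block; doubled per level.
#' @param in_channels Input channels (3 for RGB; stage 2 adds a mask channel).
#' @param loss Loss identifier (informational; the engine implements
#'   `"ce+dice"`).
#' @param learning_rate,batch_size,max_epochs Optimizer settings.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param min_delta Minimum validation-loss decrease that counts as
#'   improvement.
#' @param seed Weight-initialization and shuffling seed.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(classes = c("background", "wound"),
                       input_size = c(128L, 128L), depth_levels = 3L,
                       base_filters = 16L, in_channels = 3L,
                       loss = "ce+dice", learning_rate = 1e-3,
                       batch_size = 8L, max_epochs = 30L,
                       early_stop_patience = 10L, min_delta = 1e-4,
                       seed = 1L) {
  input_size <- as.integer(input_size)
  if (depth_levels < 2) stop("depth_levels must be >= 2")
  if (any(input_size %% 2^depth_levels != 0))
    stop(sprintf("input size must be divisible by 2^depth_levels = %d",
                 2^depth_levels))
  if (length(classes) < 2) stop("need at least 2 classes")
  structure(list(classes = classes, input_size = input_size,
                 depth_levels = as.integer(depth_levels),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels), loss = loss,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "seg_config")
}

#' Build an untrained U-Net
#'
#' Encoder-decoder with skip connections: each encoder level applies two 3x3
#' convolutions (ReLU) and halves the spatial size by 2x2 max pooling while
#' doubling the filters; the decoder mirrors it with nearest-neighbour
#' upsampling, concatenating the same-level encoder features before each
#' convolution pair; a final 1x1 convolution produces per-pixel class scores
#' at input resolution.
#'
#' @param config A [seg_config()].
#' @return An object of class `unet_model` holding the (He-initialized)
#'   weights, the config, and an empty training history.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  weights <- cpp_unet_init(config$in_channels, length(config$classes),
                           config$depth_levels, config$base_filters,
                           config$seed)
  structure(list(config = config, weights = weights, history = NULL,
                 best_epoch = NA_integer_, trained = FALSE),
            class = "unet_model")
}

#' Number of trainable parameters of a U-Net
#'
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$weights,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<unet_model> %s | %dx%d, %d levels, %d base filters, %s params%s\n",
    paste(cfg$classes, collapse = "/"), cfg$input_size[1], cfg$input_size[2],
    cfg$depth_levels, cfg$base_filters,
    format(n_params(x), big.mark = ","),
    if (x$trained) sprintf(" | trained (best epoch %d)", x$best_epoch)
    else " | untrained"))
  invisible(x)
}

# Assemble (X, y) arrays for one stage from a wound_dataset.
# Stage 1: RGB -> {background, wound}. Stage 2: RGB zeroed outside the wound
# mask plus the mask as a 4th channel -> {other, slough, necrosis}.
stage_arrays <- function(ds, stage, idx) {
  H <- dim(ds$images)[1]; W <- dim(ds$images)[2]
  n <- length(idx)
  if (stage == 1) {
    X <- ds$images[, , , idx, drop = FALSE]
    y <- array(as.integer(ds$masks[, , idx]), dim = c(H, W, n))
  } else {
    X <- array(0, dim = c(H, W, 4, n))
    for (j in seq_len(n)) {
      m <- ds$masks[, , idx[j]]
      for (ch in 1:3) X[, , ch, j] <- ds$images[, , ch, idx[j]] * m
      X[, , 4, j] <- m
    }
    y <- array(as.integer(ds$tissues[, , idx]), dim = c(H, W, n))
  }
  list(X = X, y = y)
}

#' Train a U-Net on a synthetic wound dataset
#'
#' Trains with Adam on the dataset's training split, evaluating the
#' validation split after every epoch, and stops early when validation loss
#' has not improved by more than `min_delta` for `early_stop_patience`
#' consecutive epochs. The weights from the best validation epoch are
#' retained. Deterministic for a fixed config seed.
#'
#' @param model An untrained (or previously trained) `unet_model`.
#' @param dataset A `wound_dataset` from [generate_dataset()], or a list with
#'   precomputed `X`/`y` arrays for train and validation.
#' @param stage 1 (wound bed) or 2 (tissue classes); selects inputs/labels.
#' @return The model with updated weights and a `history` data frame of
#'   per-epoch train/validation loss, accuracy, dice and IoU.
#' @export
train_unet <- function(model, dataset, stage = 1) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- model$config
  if (inherits(dataset, "wound_dataset")) {
    tr_idx <- dataset_split(dataset, "train")
    va_idx <- dataset_split(dataset, "validation")
    if (!length(tr_idx) || !length(va_idx))
      stop("dataset has an empty train or validation split")
    tr <- stage_arrays(dataset, stage, tr_idx)
    va <- stage_arrays(dataset, stage, va_idx)
  } else {
    tr <- dataset$train; va <- dataset$validation
    if (is.null(tr$X) || is.null(va$X)) stop("dataset lacks train/validation")
  }
  if (dim(tr$X)[3] != cfg$in_channels)
    stop(sprintf("config expects %d input channels, data has %d",
                 cfg$in_channels, dim(tr$X)[3]))
  fit <- cpp_unet_train(model$weights, cfg$in_channels, length(cfg$classes),
                        cfg$depth_levels, cfg$base_filters,
                        as.numeric(tr$X), dim(tr$X),
                        as.integer(tr$y),
                        as.numeric(va$X), dim(va$X),
                        as.integer(va$y),
                        cfg$learning_rate, cfg$batch_size, cfg$max_epochs,
                        cfg$early_stop_patience, cfg$min_delta, cfg$seed)
  hist <- as.data.frame(fit$history)
  names(hist) <- c("train_loss", "train_acc", "train_dice", "train_iou",
                   "val_loss", "val_acc", "val_dice", "val_iou")
  hist$epoch <- seq_len(nrow(hist))
  model$weights <- fit$weights
  model$history <- hist
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

# Forward pass returning class probabilities (H x W x K) for one image
# given as an H x W x C array.
unet_probs <- function(model, x) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) == 2) x <- array(x, dim = c(d, 1))
  d <- dim(x)
  if (d[3] != cfg$in_channels)
    stop(sprintf("expected %d channels, got %d", cfg$in_channels, d[3]))
  if (d[1] %% 2^cfg$depth_levels != 0 || d[2] %% 2^cfg$depth_levels != 0)
    stop("image size must be divisible by 2^depth_levels")
  p <- cpp_unet_predict(model$weights, cfg$in_channels, length(cfg$classes),
                        cfg$depth_levels, cfg$base_filters,
                        as.numeric(x), c(d[1], d[2], d[3], 1L))
  array(p, dim = dim(p)[1:3])
}

resize_nearest <- function(m, target) {
  ri <- pmin(floor((seq_len(target[1]) - 0.5) * nrow(m) / target[1]) + 1,
             nrow(m))
  ci <- pmin(floor((seq_len(target[2]) - 0.5) * ncol(m) / target[2]) + 1,
             ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Segment the wound bed in an RGB image (stage 1)
#'
#' Applies the stage-1 U-Net and returns a binary wound mask. Images whose
#' size differs from the model's input size are resized (nearest neighbour)
#' for inference and the mask is resized back, which preserves the wound
#' area fraction to within rounding.
#'
#' @param model A trained stage-1 `unet_model`.
#' @param rgb H x W x 3 array in [0,1].
#' @param largest_component Keep only the largest connected mask component.
#' @return Logical wound mask of the input size.
#' @export
segment_wound <- function(model, rgb, largest_component = FALSE) {
  native <- dim(rgb)[1:2]
  size <- model$config$input_size
  x <- rgb
  if (!all(native == size)) {
    x <- array(0, dim = c(size, 3))
    for (ch in 1:3) x[, , ch] <- resize_nearest(rgb[, , ch], size)
  }
  p <- unet_probs(model, x)
  mask <- p[, , 2] > p[, , 1]
  if (largest_component && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    tab <- tabulate(as.integer(lab[lab > 0]))
    mask <- matrix(as.integer(lab) == which.max(tab), size[1], size[2])
  }
  if (!all(native == size)) mask <- resize_nearest(mask, native)
  mask
}

#' Label slough and necrosis inside a wound mask (stage 2)
#'
#' Feeds the stage-2 U-Net the RGB image zeroed outside the wound mask plus
#' the mask as a fourth channel, and returns per-pixel tissue labels. Pixels
#' outside the wound mask are always "other" (0) by construction.
#'
#' @param model A trained stage-2 `unet_model`.
#' @param rgb H x W x 3 array in [0,1].
#' @param wound_mask Logical wound mask aligned to `rgb` (typically stage-1
#'   output).
#' @return Integer tissue map: 0 other, 1 slough, 2 necrosis; nonzero only
#'   inside `wound_mask`.
#' @export
segment_tissue <- function(model, rgb, wound_mask) {
  wound_mask <- as_mask(wound_mask)
  if (!all(dim(wound_mask) == dim(rgb)[1:2]))
    stop("wound_mask is not aligned to the image")
  if (!any(wound_mask))
    return(matrix(0L, nrow(wound_mask), ncol(wound_mask)))
  native <- dim(rgb)[1:2]
  size <- model$config$input_size
  m <- wound_mask
  img <- rgb
  if (!all(native == size)) {
    m <- resize_nearest(wound_mask, size)
    img <- array(0, dim = c(size, 3))
    for (ch in 1:3) img[, , ch] <- resize_nearest(rgb[, , ch], size)
  }
  x <- array(0, dim = c(size, 4))
  for (ch in 1:3) x[, , ch] <- img[, , ch] * m
  x[, , 4] <- m
  p <- unet_probs(model, x)
  lab <- apply(p, c(1, 2), which.max) - 1L
  lab[!m] <- 0L
  if (!all(native == size)) lab <- resize_nearest(lab, native)
  lab[!wound_mask] <- 0L
  lab
}

check_masks <- function(a, b) {
  if (is.numeric(a)) a <- a > 0.5
  if (is.numeric(b)) b <- b > 0.5
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  list(a = a, b = b)
}

#' Dice coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks score 1.
#'
#' @param a,b Logical (or 0/1) masks of equal shape.
#' @return Scalar in [0, 1].
#' @export
dice <- function(a, b) {
  m <- check_masks(a, b)
  sa <- sum(m$a); sb <- sum(m$b)
  if (sa + sb == 0) return(1)
  2 * sum(m$a & m$b) / (sa + sb)
}

#' Intersection over union between two masks
#'
#' `|A intersect B| / |A union B|`; two empty masks score 1.
#'
#' @inheritParams dice
#' @return Scalar in [0, 1].
#' @export
iou <- function(a, b) {
  m <- check_masks(a, b)
  u <- sum(m$a | m$b)
  if (u == 0) return(1)
  sum(m$a & m$b) / u
}

#' Tissue composition of a wound bed
#'
#' Percentage of wound-bed pixels labelled slough and necrosis.
#'
#' @param tissue Integer tissue map (0 other, 1 slough, 2 necrosis).
#' @param wound_mask Logical wound mask; tissue labels outside it are
#'   ignored.
#' @return An object of class `tissue_fractions`: `slough_pct`,
#'   `necrosis_pct`, `wound_pixels`.
#' @export
tissue_fractions <- function(tissue, wound_mask) {
  wound_mask <- as_mask(wound_mask)
  if (!all(dim(tissue) == dim(wound_mask)))
    stop("tissue map and wound mask shapes differ")
  n <- sum(wound_mask)
  if (n == 0)
    return(structure(list(slough_pct = 0, necrosis_pct = 0,
                          wound_pixels = 0L), class = "tissue_fractions"))
  tv <- tissue[wound_mask]
  structure(list(slough_pct = 100 * sum(tv == 1) / n,
                 necrosis_pct = 100 * sum(tv == 2) / n,
                 wound_pixels = as.integer(n)),
            class = "tissue_fractions")
}

#' @export
print.tissue_fractions <- function(x, ...) {
  cat(sprintf("<tissue_fractions> slough %.2f%%, necrosis %.2f%% of %d px\n",
              x$slough_pct, x$necrosis_pct, x$wound_pixels))
  invisible(x)
}

#' Binary presence call for slough and necrosis
#'
#' A tissue class is called present when it covers more than `threshold_pct`
#' of the wound bed; the default 1% ignores trace detections such as a
#' 0.03% sliver while keeping genuinely small regions.
#'
#' @param fractions A [tissue_fractions()] result.
#' @param threshold_pct Presence threshold in percent of wound pixels.
#' @return List with logicals `slough_present` and `necrosis_present`.
#' @export
presence_call <- function(fractions, threshold_pct = 1.0) {
  stopifnot(inherits(fractions, "tissue_fractions"))
  list(slough_present = fractions$slough_pct > threshold_pct,
       necrosis_present = fractions$necrosis_pct > threshold_pct)
}
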