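# The five generative augmentations on image+mask pairs.
#
# Each transform co-transforms the image (bilinear), the label mask
# (nearest) and the keep mask (nearest), and updates the sector geometry
# and the physical pixel spacing. The keep mask marks the pixels taken
# verbatim from the input; its complement is the region later synthesized
# by RePaint. Because mask and keep mask are warped with identical nearest-
# neighbour semantics and labels start inside the sector support, labeled
# pixels can never end up in the repaint region (label safety).

LV_LABEL <- 1L
MYO_LABEL <- 2L

#' A labeled sector-scan sample
#'
#' @param image H x W numeric matrix in \[0, 1\].
#' @param mask integer H x W matrix with labels 0 (background), 1 (LV),
#'   2 (MYO).
#' @param geometry optional [sector_geometry()].
#' @param spacing numeric length-2, (row, col) pixel spacing in mm/px.
#' @param provenance list of applied transforms and parameters.
#' @return object of class `labeled_sample`.
#' @export
labeled_sample <- function(image, mask, geometry = NULL, spacing = c(1, 1),
                           provenance = list()) {
  if (!identical(dim(image), dim(mask)))
    abort_invalid("image and mask shapes differ")
  if (!all(mask %in% 0:2))
    abort_invalid("mask labels must be in {0, 1, 2}")
  if (any(spacing <= 0)) abort_invalid("spacing must be > 0")
  structure(list(image = image, mask = mask, geometry = geometry,
                 spacing = as.numeric(spacing), provenance = provenance),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf("<labeled_sample> %dx%d, spacing (%.3f, %.3f) mm/px, LV %d px, MYO %d px, %d transform(s)\n",
              nrow(x$image), ncol(x$image), x$spacing[1], x$spacing[2],
              sum(x$mask == LV_LABEL), sum(x$mask == MYO_LABEL),
              length(x$provenance)))
  invisible(x)
}

#' Augmentation configuration
#'
#' Parameter ranges of the five generative augmentations and the protocol
#' constants: each of depth/tilt/width/translation is applied independently
#' with `combination_probability` when combining, and each input image is
#' augmented `n_augment_per_image` times.
#'
#' @param depth_lambda_range depth increase in pixels, default \[0, 150\].
#' @param tilt_range rotation about the sector tip in degrees, (-30, 30).
#' @param width_factor_range horizontal scale factor, (0.5, 1.5).
#' @param translation_length_range shift length in pixels, (0, 50).
#' @param combination_probability per-transform application chance, 0.5.
#' @param n_augment_per_image augmentations per input image, 5.
#' @param output_size output frame side in pixels, 256.
#' @return list of class `augmentation_config`.
#' @export
augmentation_config <- function(depth_lambda_range = c(0, 150),
                                tilt_range = c(-30, 30),
                                width_factor_range = c(0.5, 1.5),
                                translation_length_range = c(0, 50),
                                combination_probability = 0.5,
                                n_augment_per_image = 5L,
                                output_size = 256L) {
  for (rg in list(depth_lambda_range, tilt_range, width_factor_range,
                  translation_length_range))
    if (rg[1] > rg[2]) abort_invalid("augmentation ranges must be ordered")
  check_range(combination_probability, "combination_probability", 0, 1)
  structure(list(depth_lambda_range = depth_lambda_range,
                 tilt_range = tilt_range,
                 width_factor_range = width_factor_range,
                 translation_length_range = translation_length_range,
                 combination_probability = combination_probability,
                 n_augment_per_image = as.integer(n_augment_per_image),
                 output_size = as.integer(output_size)),
            class = "augmentation_config")
}

# default keep mask: the sector support (geometry if known, else any
# non-black pixel)
default_keep <- function(sample) {
  if (!is.null(sample$geometry))
    sector_support(sample$geometry, dim(sample$image)) * 1
  else
    (sample$image > 0) * 1
}

apply_warp <- function(sample, keep, src_r, src_c, geometry, record) {
  image <- warp_bilinear(sample$image, src_r, src_c)
  mask <- warp_nearest(sample$mask, src_r, src_c, fill = 0L)
  keep <- warp_nearest(keep, src_r, src_c, fill = 0)
  s2 <- sample
  s2$image <- clamp(image, 0, 1); s2$mask <- mask; s2$geometry <- geometry
  s2$provenance <- c(sample$provenance, list(record))
  list(sample = s2, keep_mask = keep)
}

#' Depth increase
#'
#' Emulates scanning at larger depth: `lambda_px` black rows are appended
#' at the bottom and the frame is resized back to its original size. The
#' resize is isotropic (the sector shrinks without distortion), so the
#' pixel spacing grows by (H + lambda)/H on both axes and the LV pixel
#' count shrinks by the square of H/(H + lambda).
#'
#' @param sample a [labeled_sample()].
#' @param lambda_px depth increase in pixels, in \[0, 150\].
#' @param keep incoming keep mask (defaults to the sector support).
#' @return list with `sample` and `keep_mask`.
#' @export
depth_increase <- function(sample, lambda_px, keep = default_keep(sample)) {
  check_range(lambda_px, "lambda_px", 0, 150)
  if (lambda_px == 0)
    return(list(sample = sample, keep_mask = keep))
  H <- nrow(sample$image); W <- ncol(sample$image)
  s <- (H + lambda_px) / H
  g <- out_grid(H, W)
  src_r <- g$r * s
  src_c <- (g$c - (W + 1) / 2) * s + (W + 1) / 2
  geometry <- sample$geometry
  if (!is.null(geometry)) {
    geometry$apex <- c(geometry$apex[1] / s,
                       (geometry$apex[2] - (W + 1) / 2) / s + (W + 1) / 2)
    geometry$radius <- geometry$radius / s
  }
  out <- apply_warp(sample, keep, src_r, src_c, geometry,
                    list(op = "depth_increase", lambda_px = lambda_px))
  out$sample$spacing <- sample$spacing * s
  out
}

#' Tilt variation
#'
#' Rotates image and mask by `theta_deg` about the sector tip; content
#' leaving the frame is cropped. Requires geometry (tilt pivot); if the
#' sample has none, the pivot defaults to top-center of the frame.
#'
#' @inheritParams depth_increase
#' @param theta_deg rotation in degrees, in (-30, 30); positive rotates
#'   the sector clockwise on screen.
#' @return list with `sample` and `keep_mask`.
#' @export
tilt <- function(sample, theta_deg, keep = default_keep(sample)) {
  check_range(theta_deg, "theta_deg", -30, 30, TRUE, TRUE)
  if (theta_deg == 0)
    return(list(sample = sample, keep_mask = keep))
  H <- nrow(sample$image); W <- ncol(sample$image)
  piv <- if (!is.null(sample$geometry)) sample$geometry$apex else c(1, (W + 1) / 2)
  th <- theta_deg * pi / 180
  g <- out_grid(H, W)
  dr <- g$r - piv[1]; dc <- g$c - piv[2]
  src_r <- piv[1] + cos(th) * dr - sin(th) * dc
  src_c <- piv[2] + sin(th) * dr + cos(th) * dc
  geometry <- sample$geometry
  if (!is.null(geometry)) geometry$axis_deg <- geometry$axis_deg + theta_deg
  apply_warp(sample, keep, src_r, src_c, geometry,
             list(op = "tilt", theta_deg = theta_deg))
}

#' Sector width adjustment
#'
#' Scales the image horizontally about the apex column by `factor`:
#' factor > 1 stretches (content is cropped laterally), factor < 1
#' squeezes toward the center (lateral gaps become black). The column
#' spacing is divided by `factor`; the resulting anisotropic spacing is
#' tracked, not corrected.
#'
#' @inheritParams depth_increase
#' @param factor horizontal scale in (0.5, 1.5).
#' @return list with `sample` and `keep_mask`.
#' @export
width_adjust <- function(sample, factor, keep = default_keep(sample)) {
  check_range(factor, "factor", 0.5, 1.5, TRUE, TRUE)
  if (factor == 1)
    return(list(sample = sample, keep_mask = keep))
  H <- nrow(sample$image); W <- ncol(sample$image)
  piv_c <- if (!is.null(sample$geometry)) sample$geometry$apex[2] else (W + 1) / 2
  g <- out_grid(H, W)
  src_r <- g$r
  src_c <- piv_c + (g$c - piv_c) / factor
  geometry <- sample$geometry
  if (!is.null(geometry)) {
    half <- geometry$opening_angle / 2 * pi / 180
    geometry$opening_angle <- 2 * atan(factor * tan(half)) * 180 / pi
  }
  out <- apply_warp(sample, keep, src_r, src_c, geometry,
                    list(op = "width_adjust", factor = factor))
  out$sample$spacing <- c(sample$spacing[1], sample$spacing[2] / factor)
  out
}

#' Translation
#'
#' Shifts the frame by a vector given as an angle (degrees counter-
#' clockwise from image-right) and a length in pixels, rounded to integer
#' pixel shifts; exposed pixels are black and content leaving the frame is
#' cropped.
#'
#' @inheritParams depth_increase
#' @param angle_deg direction in degrees CCW from image-right.
#' @param length_px shift length in pixels, in \[0, 50\].
#' @return list with `sample` and `keep_mask`.
#' @export
translate <- function(sample, angle_deg, length_px,
                      keep = default_keep(sample)) {
  check_range(length_px, "length_px", 0, 50)
  a <- angle_deg * pi / 180
  dc <- as.integer(round(length_px * cos(a)))
  dr <- as.integer(round(-length_px * sin(a)))   # CCW: positive angle moves up
  shift_int <- function(m, fill = 0) {
    out <- matrix(fill, nrow(m), ncol(m))
    storage.mode(out) <- storage.mode(m)
    src_r <- seq_len(nrow(m)) - dr; src_c <- seq_len(ncol(m)) - dc
    ok_r <- src_r >= 1 & src_r <= nrow(m); ok_c <- src_c >= 1 & src_c <= ncol(m)
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  s2 <- sample
  s2$image <- shift_int(sample$image)
  s2$mask <- shift_int(sample$mask, 0L)
  if (!is.null(s2$geometry)) s2$geometry$apex <- s2$geometry$apex + c(dr, dc)
  s2$provenance <- c(sample$provenance,
                     list(list(op = "translate", angle_deg = angle_deg,
                               length_px = length_px, dr = dr, dc = dc)))
  list(sample = s2, keep_mask = shift_int(keep))
}

#' Random combination of the four transforms
#'
#' Applies depth increase, tilt, width adjustment and translation, each
#' independently with probability `config$combination_probability`, in
#' that fixed order, with parameters drawn uniformly from the config
#' ranges. If the LV would lose more than 20% of its pixels to cropping,
#' the draw is rejected and repeated (up to 20 times).
#'
#' @param sample a [labeled_sample()].
#' @param config an [augmentation_config()].
#' @param seed integer seed.
#' @return list with `sample`, `keep_mask` and `provenance` (the drawn
#'   parameters).
#' @export
combine_transforms <- function(sample, config, seed = 1L) {
  set.seed(as.integer(seed))
  lv0 <- sum(sample$mask == LV_LABEL)
  for (attempt in seq_len(20L)) {
    draw <- list(
      depth = stats::runif(1) < config$combination_probability,
      tilt = stats::runif(1) < config$combination_probability,
      width = stats::runif(1) < config$combination_probability,
      translate = stats::runif(1) < config$combination_probability,
      lambda_px = stats::runif(1, config$depth_lambda_range[1],
                               config$depth_lambda_range[2]),
      theta_deg = stats::runif(1, config$tilt_range[1], config$tilt_range[2]),
      factor = stats::runif(1, config$width_factor_range[1],
                            config$width_factor_range[2]),
      angle_deg = stats::runif(1, 0, 360),
      length_px = stats::runif(1, config$translation_length_range[1],
                               config$translation_length_range[2]))
    cur <- list(sample = sample, keep_mask = default_keep(sample))
    if (draw$depth)
      cur <- depth_increase(cur$sample, draw$lambda_px, cur$keep_mask)
    if (draw$tilt)
      cur <- tilt(cur$sample, draw$theta_deg, cur$keep_mask)
    if (draw$width)
      cur <- width_adjust(cur$sample, draw$factor, cur$keep_mask)
    if (draw$translate)
      cur <- translate(cur$sample, draw$angle_deg, draw$length_px, cur$keep_mask)
    if (lv0 == 0 || sum(cur$sample$mask == LV_LABEL) >= 0.8 * lv0) {
      assert_label_safety(cur$sample$mask, cur$keep_mask)
      return(c(cur, list(provenance = draw)))
    }
  }
  abort_invalid("could not draw a combination keeping >= 80% of LV pixels",
                class = "echosynth_augmentation_error")
}

# the package's central guarantee: no labeled pixel in the repaint region
assert_label_safety <- function(mask, keep_mask) {
  if (any(mask > 0 & keep_mask == 0))
    stop(structure(class = c("echosynth_label_safety_error", "error", "condition"),
                   list(message = "labeled pixel in repaint region", call = NULL)))
  invisible(TRUE)
}

#' Blackout baseline
#'
#' Identical to [combine_transforms()] but the repaint region is simply
#' left black instead of being synthesized: the ablation baseline that
#' isolates the effect of repainting.
#'
#' @inheritParams combine_transforms
#' @return a [labeled_sample()] (repaint region pixels are 0).
#' @export
blackout_baseline <- function(sample, config, seed = 1L) {
  cur <- combine_transforms(sample, config, seed)
  s2 <- cur$sample
  s2$image[cur$keep_mask == 0] <- 0
  s2$provenance <- c(s2$provenance, list(list(op = "blackout")))
  s2
}

#' Sector-narrowing preprocessing for diffusion training
#'
#' Randomly narrowing the sector angle by up to 20 degrees (removing
#' pixels along the peripheral scan lines) and stretching the cut sector
#' back to the full frame adds sector-width variety to the diffusion
#' model's training set. Applied only when preparing DDPM training data.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param geometry the frame's [sector_geometry()].
#' @param delta_deg angle reduction in degrees, \[0, 20\].
#' @return list with `image` and the post-stretch `geometry`.
#' @export
narrow_width_pretrain <- function(image, geometry, delta_deg) {
  check_range(delta_deg, "delta_deg", 0, 20)
  if (delta_deg >= geometry$opening_angle)
    abort_invalid("`delta_deg` would close the sector")
  if (delta_deg == 0) return(list(image = image, geometry = geometry))
  new_angle <- geometry$opening_angle - delta_deg
  cut_geom <- geometry; cut_geom$opening_angle <- new_angle
  cut <- image * sector_support(cut_geom, dim(image))
  f <- tan(geometry$opening_angle / 2 * pi / 180) /
       tan(new_angle / 2 * pi / 180)
  H <- nrow(image); W <- ncol(image)
  g <- out_grid(H, W)
  src_c <- geometry$apex[2] + (g$c - geometry$apex[2]) / f
  out <- warp_bilinear(cut, g$r, src_c)
  out_geom <- geometry
  out_geom$opening_angle <- 2 * atan(f * tan(new_angle / 2 * pi / 180)) * 180 / pi
  list(image = clamp(out, 0, 1), geometry = out_geom)
}

#' Stride subsampling of a cine sequence
#'
#' Walks the sequence keeping a frame, then skipping N - 1 frames with N
#' redrawn uniformly in `stride_range` at every kept frame. Reduces the
#' diffusion training set while preserving variety (consecutive frames are
#' nearly identical at high frame rates).
#'
#' @param frames list (or vector) of frames.
#' @param stride_range inclusive integer range, default \[8, 12\].
#' @param seed integer seed.
#' @return integer indices of the kept frames.
#' @export
subsample_every_nth <- function(frames, stride_range = c(8L, 12L), seed = 1L) {
  n <- length(frames)
  if (n < 1L) abort_invalid("`frames` must be non-empty")
  set.seed(as.integer(seed))
  keep <- integer(0)
  i <- 1L
  while (i <= n) {
    keep <- c(keep, i)
    i <- i + sample(seq.int(stride_range[1], stride_range[2]), 1L)
  }
  keep
}

#' Generative augmentation of a labeled dataset
#'
#' For every input sample, emits the original plus
#' `config$n_augment_per_image` samples produced by a random transform
#' combination followed by RePaint synthesis of the complement of the keep
#' mask. Labeled pixels of every emitted sample are bit-identical to the
#' transformed (pre-repaint) image, asserted at run time. A failed repaint
#' (non-finite output) causes the sample's transform to be redrawn, at
#' most 3 times.
#'
#' @param samples list of [labeled_sample()].
#' @param predictor predictor contract object matching the frame size.
#' @param schedule sampling `noise_schedule`.
#' @param config an [augmentation_config()].
#' @param seed master seed.
#' @param jump_length,n_resample RePaint schedule parameters.
#' @return list of labeled samples of length `6 * length(samples)`.
#' @export
augment_dataset <- function(samples, predictor, schedule, config, seed = 1L,
                            jump_length = 10L, n_resample = 10L) {
  if (length(samples) == 0L) abort_invalid("`samples` must be non-empty")
  out <- vector("list", length(samples) * (config$n_augment_per_image + 1L))
  k <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    k <- k + 1L; out[[k]] <- s
    for (j in seq_len(config$n_augment_per_image)) {
      for (retry in 0:3) {
        sd_ij <- derive_seed(seed, sprintf("augment/%d/%d/%d", i, j, retry))
        tr <- combine_transforms(s, config, sd_ij)
        painted <- repaint(predictor, schedule, tr$sample$image, tr$keep_mask,
                           jump_length, n_resample,
                           seed = derive_seed(sd_ij, "repaint"))
        if (all(is.finite(painted))) break
        if (retry == 3L)
          abort_invalid(sprintf("repaint failed for sample %d augmentation %d", i, j),
                        class = "echosynth_augmentation_error")
      }
      pre <- tr$sample$image
      if (!identical(painted[tr$sample$mask > 0], pre[tr$sample$mask > 0]))
        stop("labeled pixels altered by repaint")  # never reachable by construction
      aug <- tr$sample
      aug$image <- painted
      aug$provenance <- c(aug$provenance,
                          list(list(op = "repaint", seed = sd_ij,
                                    jump_length = jump_length,
                                    n_resample = n_resample,
                                    params = tr$provenance)))
      k <- k + 1L; out[[k]] <- aug
    }
  }
  out
}
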