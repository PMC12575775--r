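# Synthetic speckle phantom: sector images with LV/MYO masks and cine
# sequences with prescribed ejection fraction. Every emitted sample comes
# with exact ground truth (geometry, masks, volumes), which makes all
# downstream modules testable without any data download. This is not a
# physical ultrasound simulator: there is no point-spread function and no
# scan-conversion artifact, just B-mode-like contrast (dark cavity, bright
# myocardium) under smoothed multiplicative speckle.

#' Phantom configuration
#'
#' Acquisition-parameter distributions default to the published
#' characteristics of the two source datasets: the `hunt4like` preset uses
#' depth 127.8 +/- 12.2 mm, sector angle 65.5 +/- 4.0 degrees and EF
#' 59.1 +/- 6.6%; the `camuslike` preset uses 151.6 +/- 24.5 mm,
#' 75.2 +/- 5.8 degrees and 52.5 +/- 12.3%.
#'
#' @param preset "hunt4like" or "camuslike".
#' @param image_size frame side in pixels (default 256).
#' @param lv_long_semi_range LV long semi-axis range in mm.
#' @param lv_short_semi_range LV short semi-axis range in mm.
#' @param myo_thickness_mm myocardial wall thickness in mm.
#' @param speckle_scale multiplicative speckle amplitude in \[0, 1\].
#' @param speckle_smooth speckle correlation length in pixels.
#' @param depth_mean,depth_sd,angle_mean,angle_sd,ef_mean,ef_sd override
#'   the preset distributions (mm, degrees, percent).
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(preset = c("hunt4like", "camuslike"),
                           image_size = 256L,
                           lv_long_semi_range = c(36, 46),
                           lv_short_semi_range = c(22, 30),
                           myo_thickness_mm = 9,
                           speckle_scale = 0.35,
                           speckle_smooth = 1.5,
                           depth_mean = NULL, depth_sd = NULL,
                           angle_mean = NULL, angle_sd = NULL,
                           ef_mean = NULL, ef_sd = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    hunt4like = list(depth = c(127.8, 12.2), angle = c(65.5, 4.0), ef = c(59.1, 6.6)),
    camuslike = list(depth = c(151.6, 24.5), angle = c(75.2, 5.8), ef = c(52.5, 12.3)))
  if (myo_thickness_mm <= 0) abort_invalid("`myo_thickness_mm` must be > 0")
  cfg <- list(preset = preset, image_size = as.integer(image_size),
              depth_mean = depth_mean %||% def$depth[1],
              depth_sd = depth_sd %||% def$depth[2],
              angle_mean = angle_mean %||% def$angle[1],
              angle_sd = angle_sd %||% def$angle[2],
              ef_mean = ef_mean %||% def$ef[1],
              ef_sd = ef_sd %||% def$ef[2],
              lv_long_semi_range = lv_long_semi_range,
              lv_short_semi_range = lv_short_semi_range,
              myo_thickness_mm = myo_thickness_mm,
              speckle_scale = speckle_scale,
              speckle_smooth = speckle_smooth)
  if (cfg$depth_sd < 0 || cfg$angle_sd < 0 || cfg$ef_sd < 0)
    abort_invalid("standard deviations must be >= 0")
  structure(cfg, class = "phantom_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw acquisition geometry; spacing so that the sector radius spans the
# configured depth
draw_geometry <- function(config, H) {
  depth_mm <- max(stats::rnorm(1, config$depth_mean, config$depth_sd), 60)
  angle <- min(max(stats::rnorm(1, config$angle_mean, config$angle_sd), 30), 120)
  apex_row <- 0.03 * H
  apex_col <- (H + 1) / 2 + stats::runif(1, -0.02, 0.02) * H
  radius <- 0.94 * H - apex_row
  spacing <- depth_mm / radius
  list(geometry = sector_geometry(c(apex_row, apex_col), angle, radius),
       depth_mm = depth_mm, spacing = spacing)
}

# rasterize LV + MYO for an ellipse cross-section (mm coordinates)
render_lv_masks <- function(H, geometry, spacing, center_px, long_semi_mm,
                            short_semi_mm, orient_deg, thickness_mm) {
  g <- out_grid(H, H)
  u_mm <- (g$r - center_px[1]) * spacing
  v_mm <- (g$c - center_px[2]) * spacing
  th <- orient_deg * pi / 180
  lon <- cos(th) * u_mm + sin(th) * v_mm
  lat <- -sin(th) * u_mm + cos(th) * v_mm
  lv <- (lon / long_semi_mm)^2 + (lat / short_semi_mm)^2 <= 1
  outer_ <- (lon / (long_semi_mm + thickness_mm))^2 +
            (lat / (short_semi_mm + thickness_mm))^2 <= 1
  mask <- matrix(0L, H, H)
  mask[outer_] <- MYO_LABEL
  mask[lv] <- LV_LABEL
  list(mask = mask, outer = outer_)
}

phantom_intensity <- function(mask, support, config) {
  H <- nrow(mask)
  base <- matrix(0, H, H)
  base[support] <- 0.35
  base[mask == MYO_LABEL] <- 0.65
  base[mask == LV_LABEL] <- 0.08
  field <- conv_sep2d(matrix(stats::rnorm(H * H), H, H),
                      gaussian_kernel1d(config$speckle_smooth))
  sq <- field^2
  speckle <- 1 + config$speckle_scale * (sq / mean(sq) - 1)
  img <- clamp(base * speckle, 0, 1)
  img[!support] <- 0
  img
}

#' Generate one phantom sample
#'
#' Draws depth, sector angle and LV pose from the configured
#' distributions, renders the sector support, places an ellipse-section LV
#' cavity wrapped by a myocardial annulus inside it, and applies smoothed
#' multiplicative speckle. Masks, geometry and spacing are exact.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed (same seed, same sample).
#' @return a [labeled_sample()]; attribute `ground_truth` holds the drawn
#'   parameters (depth_mm, angle, ellipse pose and semi-axes).
#' @export
generate_sample <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  H <- config$image_size
  # acquisition geometry is drawn once so the configured depth/angle
  # distributions are not biased by LV-fit rejections
  geo <- draw_geometry(config, H)
  for (attempt in seq_len(20L)) {
    long_mm <- stats::runif(1, config$lv_long_semi_range[1], config$lv_long_semi_range[2])
    short_mm <- stats::runif(1, config$lv_short_semi_range[1], config$lv_short_semi_range[2])
    shrink <- 0.97^(attempt - 1)   # progressively smaller LV if it won't fit
    long_mm <- long_mm * shrink; short_mm <- short_mm * shrink
    orient <- stats::runif(1, -12, 12)
    # feasible depth window for the outer (annulus) ellipse inside the cone:
    # nearest admissible center distance comes from the tangency condition
    # of an axis-aligned ellipse against the sector edge lines
    L <- (long_mm + config$myo_thickness_mm) / geo$spacing
    S <- (short_mm + config$myo_thickness_mm) / geo$spacing
    h <- geo$geometry$opening_angle / 2 * pi / 180
    phi <- atan(S / (L * tan(h)))
    lo <- (L * cos(phi) + S * sin(phi) / tan(h)) * 1.1   # margin for orient
    hi <- geo$geometry$radius - L - 2
    if (lo >= hi) next
    dist_px <- stats::runif(1, lo, min(hi, lo + 0.08 * H))
    center <- geo$geometry$apex + c(dist_px, 0)
    rl <- render_lv_masks(H, geo$geometry, geo$spacing, center, long_mm,
                          short_mm, orient, config$myo_thickness_mm)
    support <- sector_support(geo$geometry, c(H, H))
    if (all(support[rl$outer])) {
      img <- phantom_intensity(rl$mask, support, config)
      s <- labeled_sample(img, rl$mask, geo$geometry,
                          spacing = rep(geo$spacing, 2),
                          provenance = list(list(op = "phantom", seed = seed)))
      attr(s, "ground_truth") <- list(depth_mm = geo$depth_mm,
                                      angle_deg = geo$geometry$opening_angle,
                                      long_semi_mm = long_mm,
                                      short_semi_mm = short_mm,
                                      orient_deg = orient,
                                      center_px = center)
      return(s)
    }
  }
  abort_invalid("LV does not fit in the sector after 20 redraws",
                class = "echosynth_generation_error")
}

#' Generate a cine phantom with prescribed ejection fraction
#'
#' Models the LV as a 3-D ellipsoid with semi-axes (a, b, c) whose volume
#' oscillates sinusoidally between EDV and ESV = (1 - ef_target) * EDV
#' (frame 1 is end-diastole). The two orthogonal long-axis cross-sections
#' are rendered as the A2C (a x b) and A4C (a x c) view masks per frame.
#' Ground-truth volumes come from the ellipsoid closed form
#' (4/3) pi a b c.
#'
#' @param config a [phantom_config()].
#' @param n_frames frames per cycle (>= 2).
#' @param ef_target prescribed EF in (0, 1).
#' @param seed integer seed.
#' @return list with `a2c` and `a4c` (each a list of [labeled_sample()]),
#'   and `truth`: ed_index, es_index, edv_ml, esv_ml, ef, semi-axes.
#' @export
generate_cine <- function(config, n_frames = 10L, ef_target = 0.6, seed = 1L) {
  check_range(ef_target, "ef_target", 0, 1, TRUE, TRUE)
  if (n_frames < 2L) abort_invalid("`n_frames` must be >= 2")
  set.seed(as.integer(seed))
  H <- config$image_size
  geo <- draw_geometry(config, H)
  a <- stats::runif(1, config$lv_long_semi_range[1], config$lv_long_semi_range[2])
  b <- stats::runif(1, config$lv_short_semi_range[1], config$lv_short_semi_range[2])
  cc <- b * stats::runif(1, 0.9, 1.1)
  edv <- 4 / 3 * pi * a * b * cc / 1000     # ml
  esv <- (1 - ef_target) * edv
  phase <- (seq_len(n_frames) - 1) / n_frames
  vol <- esv + (edv - esv) * (1 + cos(2 * pi * phase)) / 2
  scale <- (vol / edv)^(1 / 3)
  dist_px <- (a + config$myo_thickness_mm) / geo$spacing * 1.15
  center <- geo$geometry$apex + c(dist_px, 0)
  support <- sector_support(geo$geometry, c(H, H))
  mk_frame <- function(s, short_semi) {
    rl <- render_lv_masks(H, geo$geometry, geo$spacing, center, a * s,
                          short_semi * s, 0, config$myo_thickness_mm)
    img <- phantom_intensity(rl$mask, support, config)
    labeled_sample(img, rl$mask, geo$geometry, rep(geo$spacing, 2))
  }
  a2c <- lapply(scale, mk_frame, short_semi = b)
  a4c <- lapply(scale, mk_frame, short_semi = cc)
  list(a2c = a2c, a4c = a4c,
       truth = list(ed_index = 1L, es_index = which.min(vol),
                    edv_ml = edv, esv_ml = esv, ef = ef_target,
                    semi_axes_mm = c(a = a, b = b, c = cc),
                    volumes_ml = vol))
}
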