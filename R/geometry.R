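# Sector geometry: the fan-shaped field of view of a phased-array probe,
# described by its apex (virtual transducer position), opening angle,
# radius (depth extent in pixels) and axis direction.

#' Sector geometry descriptor
#'
#' @param apex numeric length-2, (row, col) of the sector tip in pixels
#'   (1-based, row 1 at top). May lie above the frame.
#' @param opening_angle opening angle in degrees, in (0, 180).
#' @param radius depth extent in pixels (> 0).
#' @param axis_deg direction of the sector axis in degrees clockwise from
#'   straight down (default 0).
#' @return object of class `sector_geometry`.
#' @export
sector_geometry <- function(apex, opening_angle, radius, axis_deg = 0) {
  check_range(opening_angle, "opening_angle", 0, 180, TRUE, TRUE)
  if (radius <= 0) abort_invalid("`radius` must be > 0")
  structure(list(apex = as.numeric(apex), opening_angle = opening_angle,
                 radius = radius, axis_deg = axis_deg),
            class = "sector_geometry")
}

#' @export
print.sector_geometry <- function(x, ...) {
  cat(sprintf("<sector_geometry> apex (%.1f, %.1f), angle %.1f deg, radius %.1f px, axis %.1f deg\n",
              x$apex[1], x$apex[2], x$opening_angle, x$radius, x$axis_deg))
  invisible(x)
}

#' Render the binary support of a sector
#'
#' @param geometry a [sector_geometry()].
#' @param dim integer length-2 (rows, cols) of the frame.
#' @return logical matrix, TRUE inside the sector.
#' @export
sector_support <- function(geometry, dim) {
  H <- dim[1]; W <- dim[2]
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- r - geometry$apex[1]
  dc <- cc - geometry$apex[2]
  dist <- sqrt(dr^2 + dc^2)
  # angle of each pixel from the axis direction (0 = along the axis)
  ax <- geometry$axis_deg * pi / 180
  ang <- atan2(dc, dr)                       # 0 = straight down
  dang <- abs(((ang - ax + pi) %% (2 * pi)) - pi)
  dist <= geometry$radius & dang <= geometry$opening_angle / 2 * pi / 180 & dist > 0
}

# Largest 4-connected component of a logical matrix, by iterative minimum-
# label propagation (vectorized; converges in O(component diameter) sweeps).
largest_component <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  lab[bin] <- seq_len(sum(bin))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    nb <- pmax(shift(lab, 1, 0), shift(lab, -1, 0),
               shift(lab, 0, 1), shift(lab, 0, -1))
    new <- ifelse(bin & nb > lab, nb, lab)
    if (identical(new, lab)) break
    lab <- new
  }
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

#' Estimate sector geometry from an image
#'
#' The support is the largest connected component above
#' `intensity_threshold`; the apex is the intersection of straight lines
#' fitted to the two lateral sector edges; the opening angle comes from the
#' edge slopes and the radius from the farthest support pixel.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param intensity_threshold foreground threshold (default 0.02).
#' @return list with `geometry` (a [sector_geometry()]) and `support`
#'   (logical matrix).
#' @export
detect_sector <- function(image, intensity_threshold = 0.02) {
  fg <- image > intensity_threshold
  if (!any(fg))
    abort_invalid("no foreground above threshold", class = "echosynth_detection_error")
  supp <- largest_component(fg)
  rows_present <- which(rowSums(supp) > 0)
  top <- min(rows_present); bottom <- max(rows_present)
  if (mean(supp) > 0.95) {
    # essentially a full frame: no lateral edges to fit
    abort_invalid("support fills the frame; sector edges undetectable",
                  class = "echosynth_detection_error")
  }
  # fit the straight lateral edges on the upper portion of the support,
  # clear of the bottom arc
  fit_rows <- rows_present[rows_present <= top + 0.55 * (bottom - top)]
  fit_rows <- fit_rows[-seq_len(min(3L, length(fit_rows) - 2L))]  # skip apex tip
  left  <- vapply(fit_rows, function(r) which(supp[r, ])[1], 0)
  right <- vapply(fit_rows, function(r) { w <- which(supp[r, ]); w[length(w)] }, 0)
  fl <- stats::lm.fit(cbind(1, fit_rows), left)$coefficients
  fr <- stats::lm.fit(cbind(1, fit_rows), right)$coefficients
  apex_row <- (fr[1] - fl[1]) / (fl[2] - fr[2])
  apex_col <- fl[1] + fl[2] * apex_row
  half_l <- atan(fl[2]); half_r <- atan(fr[2])
  opening <- (half_r - half_l) * 180 / pi
  axis <- (half_r + half_l) / 2 * 180 / pi
  idx <- which(supp, arr.ind = TRUE)
  radius <- max(sqrt((idx[, 1] - apex_row)^2 + (idx[, 2] - apex_col)^2))
  list(geometry = sector_geometry(c(apex_row, apex_col),
                                  min(opening, 179.9), radius, axis),
       support = supp)
}

# ---- warping primitives ------------------------------------------------

# Inverse-map warp: src_r/src_c give, for every output pixel, the source
# coordinate it pulls from (1-based, fractional). Outside the frame -> fill.
warp_bilinear <- function(img, src_r, src_c, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r)); v[] <- fill
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * get(r0, c0) +
       (1 - fr) * fc       * get(r0, c0 + 1) +
       fr       * (1 - fc) * get(r0 + 1, c0) +
       fr       * fc       * get(r0 + 1, c0 + 1)
  out <- ifelse(src_r < 0.5 | src_r > H + 0.5 | src_c < 0.5 | src_c > W + 0.5,
                fill, v)
  matrix(out, nrow(src_r), ncol(src_r))
}

warp_nearest <- function(img, src_r, src_c, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r <- round(src_r); c <- round(src_c)
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  v <- rep(fill, length(r))
  v[ok] <- img[cbind(r[ok], c[ok])]
  out <- matrix(v, nrow(src_r), ncol(src_r))
  storage.mode(out) <- storage.mode(img)
  out
}

# output-grid coordinate matrices
out_grid <- function(H, W) {
  list(r = matrix(seq_len(H), H, W), c = matrix(seq_len(W), H, W, byrow = TRUE))
}
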