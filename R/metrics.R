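# Segmentation overlap/boundary metrics and SSIM retrieval.

#' Dice overlap coefficient
#'
#' 2|A n B| / (|A| + |B|) for a given label; 1 when both sets are empty.
#'
#' @param mask_a,mask_b integer label masks of equal shape.
#' @param label label value to compare (default LV = 1).
#' @return scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b, label = 1L) {
  if (!identical(dim(mask_a), dim(mask_b)))
    abort_invalid("mask shapes differ")
  a <- mask_a == label; b <- mask_b == label
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# boundary pixels: set pixels with a 4-neighbour outside the set (frame
# border counts as outside)
boundary_pixels <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- bin
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
           pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(bin & !inner, arr.ind = TRUE)
}

#' Hausdorff distance between two label boundaries, in millimetres
#'
#' Classical symmetric Hausdorff distance between the boundary pixel sets
#' of a label, with per-axis pixel spacing applied before distances.
#' `percentile = 95` gives the HD95 variant.
#'
#' @inheritParams dice
#' @param spacing numeric length-2 (row, col) spacing in mm/px.
#' @param percentile directed distances are aggregated by this percentile
#'   (100 = classical maximum).
#' @return distance in mm.
#' @export
hausdorff_mm <- function(mask_a, mask_b, label = 1L, spacing = c(1, 1),
                         percentile = 100) {
  if (!identical(dim(mask_a), dim(mask_b)))
    abort_invalid("mask shapes differ")
  a <- boundary_pixels(mask_a == label)
  b <- boundary_pixels(mask_b == label)
  if (nrow(a) == 0 || nrow(b) == 0)
    abort_invalid("empty label set: Hausdorff undefined",
                  class = "echosynth_undefined_metric")
  am <- sweep(a, 2, spacing, "*")
  bm <- sweep(b, 2, spacing, "*")
  dir_d <- function(x, y) {
    nn <- FNN::get.knnx(y, x, k = 1)$nn.dist[, 1]
    if (percentile >= 100) max(nn) else stats::quantile(nn, percentile / 100, names = FALSE)
  }
  max(dir_d(am, bm), dir_d(bm, am))
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma 1.5),
#' K1 = 0.01, K2 = 0.03, dynamic range 1; window means are computed in
#' valid mode (a 5-pixel border is excluded from the average).
#'
#' @param image_a,image_b matrices of equal shape with values in \[0, 1\].
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(image_a, image_b) {
  if (!identical(dim(image_a), dim(image_b)))
    abort_invalid("image shapes differ")
  k <- gaussian_kernel1d(1.5, radius = 5L)
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- conv_sep2d(image_a, k); mu_b <- conv_sep2d(image_b, k)
  saa <- conv_sep2d(image_a^2, k) - mu_a^2
  sbb <- conv_sep2d(image_b^2, k) - mu_b^2
  sab <- conv_sep2d(image_a * image_b, k) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  H <- nrow(s); W <- ncol(s)
  if (H > 10 && W > 10) s <- s[6:(H - 5), 6:(W - 5)]
  mean(s)
}

#' Rank candidates by similarity to a query image
#'
#' Orders a candidate set by decreasing [ssim()] against the query; ties
#' are broken by candidate index (stable).
#'
#' @param query matrix in \[0, 1\].
#' @param candidates list of matrices of the same shape.
#' @return list with `order` (indices, best first) and `scores` (SSIM per
#'   candidate, in input order).
#' @export
rank_by_ssim <- function(query, candidates) {
  if (length(candidates) == 0) abort_invalid("empty candidate set")
  scores <- vapply(candidates, function(cd) ssim(query, cd), 0)
  list(order = order(-scores, seq_along(scores)), scores = scores)
}
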