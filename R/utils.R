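#' @keywords internal
"_PACKAGE"

# Internal helpers: argument checking, value ranges, seed derivation.

abort_invalid <- function(msg, class = "echosynth_invalid_argument") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a finite numeric scalar", name))
}

check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  stopifnot_scalar_number(x, name)
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    abort_invalid(sprintf("`%s` = %g outside %s%g, %g%s", name, x,
                          if (lo_open) "(" else "[", lo, hi,
                          if (hi_open) ")" else "]"))
  invisible(x)
}

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

#' Convert between image ([0,1]) and latent ([-1,1]) value ranges
#'
#' The diffusion core works on latents in \[-1, 1\]; images at module
#' boundaries are in \[0, 1\]. These two helpers apply the affine map.
#'
#' @param x numeric array.
#' @return numeric array of the same shape.
#' @export
image_to_latent <- function(x) 2 * x - 1

#' @rdname image_to_latent
#' @export
latent_to_image <- function(x) (x + 1) / 2

#' Derive a child seed from a master seed and a tag
#'
#' All randomness in the package flows from one master seed. Stage- and
#' operation-level seeds are derived deterministically by hashing the tag
#' string into the master seed (documented splitting rule), so reruns with
#' the same master seed reproduce every artifact while distinct stages get
#' decorrelated streams.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer (e.g. "phantom/3").
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot_scalar_number(seed, "seed")
  h <- 0
  for (b in utf8ToInt(as.character(tag))) h <- (h * 131 + b) %% 2147483647
  as.integer((seed %% 2147483647 + h * 2654435) %% 2147483647)
}

# separable Gaussian smoothing with reflected edges; used by the phantom
# speckle model and SSIM.
gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

conv_sep2d <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  pad_idx <- function(n) c(pmin(pmax(seq_len(n + 2 * r) - r, 1L), n))
  # reflect would be nicer but clamp padding is fine for internal use
  A <- img[pad_idx(nrow(img)), , drop = FALSE]
  A <- apply(A, 2, function(col) stats::filter(col, k, sides = 2))[(r + 1L):(r + nrow(img)), , drop = FALSE]
  A <- A[, pad_idx(ncol(img)), drop = FALSE]
  A <- t(apply(A, 1, function(row) stats::filter(row, k, sides = 2)))[, (r + 1L):(r + ncol(img)), drop = FALSE]
  A
}
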