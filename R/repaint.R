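# Mask-guided inpainting: keep known pixels, synthesize the rest.
#
# After each reverse diffusion step the part of the latent that belongs to
# the known region is replaced by an appropriately noised version of the
# known image, so only the complement of the keep mask is ever synthesized.
# Periodic forward "jumps" re-noise the composite and let the model
# harmonise the generated content with the kept content.

#' Build a RePaint jump schedule
#'
#' The descending sequence T..1 is split into blocks of `jump_length`
#' reverse steps. After each block the chain jumps forward by the block
#' length (one-step forward transitions) and redoes the block,
#' `n_resample` times. The result is encoded as a signed integer vector:
#' a positive entry t is a reverse step x_t -> x_\{t-1\}; a negative entry
#' -t is a one-step forward noising x_\{t-1\} -> x_t.
#'
#' With `n_resample = 0` this is the plain descending sequence. For a full
#' schedule the total length is `T + 2 * jump_length * n_resample * B`
#' where B is the number of blocks.
#'
#' @param T_sampling number of sampling steps.
#' @param jump_length block length (>= 1).
#' @param n_resample number of resampling passes per block (>= 0).
#' @return signed integer vector of steps.
#' @export
build_jump_schedule <- function(T_sampling, jump_length = 10L, n_resample = 10L) {
  if (jump_length < 1) abort_invalid("`jump_length` must be >= 1")
  if (n_resample < 0) abort_invalid("`n_resample` must be >= 0")
  out <- integer(0)
  t <- as.integer(T_sampling)
  while (t >= 1L) {
    block <- seq.int(t, max(t - jump_length + 1L, 1L))
    out <- c(out, block)
    t_end <- min(block) - 1L
    if (n_resample > 0L) {
      up <- seq.int(t_end + 1L, t_end + length(block))
      loop <- c(-up, rev(up))
      out <- c(out, rep(loop, n_resample))
    }
    t <- t_end
  }
  out
}

#' RePaint a latent given a keep mask
#'
#' Core inference loop on flattened latents. `known` and `keep` are n x d
#' matrices (or vectors); `keep` is 1 where the pixel is taken from the
#' known latent and 0 where it is synthesized. At each reverse step t the
#' known region is substituted with a draw from q(x_\{t-1\} | x_0 = known)
#' (one-shot form), and at step 0 with the clean known latent, so the kept
#' region of the output is bit-identical to the input.
#'
#' @param predictor predictor contract object.
#' @param schedule `noise_schedule` used for sampling.
#' @param known known latent (values in \[-1, 1\]).
#' @param keep binary mask of the same shape.
#' @param jump_length,n_resample see [build_jump_schedule()].
#' @param seed integer seed (deterministic output).
#' @param noise_known one of "one-shot" (default: the known region is
#'   noised directly from the clean latent at every step) or "per-step"
#'   (the known trajectory is built by iterated single forward steps).
#' @return latent of the same shape; kept entries equal `known` exactly.
#' @export
repaint_latent <- function(predictor, schedule, known, keep,
                           jump_length = 10L, n_resample = 10L, seed = 1L,
                           noise_known = c("one-shot", "per-step")) {
  noise_known <- match.arg(noise_known)
  if (length(known) != length(keep))
    abort_invalid("`keep` mask shape must equal image shape")
  if (!all(keep %in% c(0, 1))) abort_invalid("`keep` mask must be binary")
  set.seed(as.integer(seed))
  plan <- build_jump_schedule(schedule$T, jump_length, n_resample)
  rn <- function() {
    z <- stats::rnorm(length(known))
    if (!is.null(dim(known))) dim(z) <- dim(known)
    z
  }
  x <- rn()
  known_traj <- known  # per-step mode: forward trajectory of the known image
  for (e in plan) {
    if (e > 0L) {
      t <- e
      x_rev <- p_sample_step(predictor, x, t, schedule, noise = rn())
      x_known <- if (t - 1L >= 1L) {
        if (noise_known == "one-shot") q_sample(known, t - 1L, rn(), schedule)
        else forward_noise_per_step(known_traj, t - 1L, schedule)
      } else known
      x <- keep * x_known + (1 - keep) * x_rev
    } else {
      t <- -e
      x <- sqrt(1 - schedule$beta[t]) * x + sqrt(schedule$beta[t]) * rn()
    }
  }
  out <- keep * known + (1 - keep) * clamp(x)
  if (!is.null(dim(known))) dim(out) <- dim(known)
  out
}

# iterated single-step forward noising of the known image down to level t
forward_noise_per_step <- function(known, t, schedule) {
  x <- known
  for (s in seq_len(t))
    x <- sqrt(1 - schedule$beta[s]) * x + sqrt(schedule$beta[s]) *
      stats::rnorm(length(known))
  x
}

#' RePaint an image
#'
#' Image-level wrapper around [repaint_latent()]: converts a \[0, 1\]
#' grayscale image to the latent range, repaints the complement of
#' `keep_mask`, and converts back. Pixels with `keep_mask == 1` are copied
#' from `image` bit-identically.
#'
#' @param predictor predictor contract object (latent dimensionality must
#'   equal `length(image)`).
#' @param schedule sampling `noise_schedule`.
#' @param image H x W matrix in \[0, 1\].
#' @param keep_mask binary H x W matrix; 1 = keep.
#' @inheritParams repaint_latent
#' @return H x W matrix in \[0, 1\].
#' @export
repaint <- function(predictor, schedule, image, keep_mask,
                    jump_length = 10L, n_resample = 10L, seed = 1L,
                    noise_known = "one-shot") {
  if (!identical(dim(image), dim(keep_mask)))
    abort_invalid("`keep_mask` shape must equal image shape")
  lat <- repaint_latent(predictor, schedule,
                        matrix(image_to_latent(as.numeric(image)), 1L),
                        matrix(as.numeric(keep_mask), 1L),
                        jump_length, n_resample, seed, noise_known)
  out <- latent_to_image(lat)
  dim(out) <- dim(image)
  out[keep_mask == 1] <- image[keep_mask == 1]
  out
}
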