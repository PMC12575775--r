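# Noise schedule and closed-form Gaussian diffusion quantities.
#
# The forward process q(x_t | x_{t-1}) = N(sqrt(1 - beta_t) x_{t-1}, beta_t I)
# gradually turns an image into approximately white Gaussian noise over T
# steps. Everything downstream (forward marginals, the closed-form posterior
# q(x_{t-1} | x_t, x0), reverse sampling) is parameterised by the per-step
# variances beta_t and the cumulative products alpha_bar_t.

#' Build a cosine noise schedule
#'
#' Constructs the squared-cosine schedule
#' \eqn{\bar\alpha_t = f(t)/f(0)} with
#' \eqn{f(t) = \cos^2\left(\frac{t/T + s}{1 + s}\cdot\frac{\pi}{2}\right)},
#' \eqn{s = 0.008}, from which per-step variances
#' \eqn{\beta_t = 1 - \bar\alpha_t/\bar\alpha_{t-1}} are derived and clipped
#' at 0.999. Compared to a linear schedule this destroys information more
#' slowly at the start of the chain, which improves sample quality for
#' image data.
#'
#' @param T_steps positive integer, number of diffusion steps.
#' @param s small offset preventing a singular first step (default 0.008).
#' @return an object of class `noise_schedule`: a list with `T`, `beta`,
#'   `alpha`, `alpha_bar` (cumulative product of `alpha`), and
#'   `posterior_variance` \eqn{\tilde\beta_t = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\beta_t}.
#' @export
build_cosine_schedule <- function(T_steps, s = 0.008) {
  if (!is.numeric(T_steps) || length(T_steps) != 1L || is.na(T_steps) ||
      T_steps < 1 || T_steps != round(T_steps))
    abort_invalid("`T_steps` must be a positive integer")
  T_steps <- as.integer(T_steps)
  f <- function(t) cos(((t / T_steps + s) / (1 + s)) * pi / 2)^2
  ab <- f(0:T_steps) / f(0)
  beta <- pmin(1 - ab[-1] / ab[-length(ab)], 0.999)
  new_noise_schedule(beta)
}

# Assemble a schedule from raw betas; alpha_bar is always the running
# product of alpha so the NoiseSchedule invariants hold exactly.
new_noise_schedule <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) abort_invalid("all beta_t must lie in (0,1)")
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-length(alpha_bar)])
  structure(list(
    T = length(beta),
    beta = beta,
    alpha = alpha,
    alpha_bar = alpha_bar,
    alpha_bar_prev = alpha_bar_prev,
    posterior_variance = (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
  ), class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> T = %d, beta in [%.3g, %.3g], alpha_bar_T = %.3g\n",
              x$T, min(x$beta), max(x$beta), x$alpha_bar[x$T]))
  invisible(x)
}

check_t <- function(t, schedule, lo = 1L) {
  if (!is.numeric(t) || length(t) < 1L || any(t != round(t)) ||
      any(t < lo) || any(t > schedule$T))
    abort_invalid(sprintf("timestep out of range [%d, %d]", lo, schedule$T),
                  class = "echosynth_range_error")
  as.integer(t)
}

#' Sample from the forward marginal q(x_t | x_0)
#'
#' Returns \eqn{\sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#' The noise is caller-supplied so the operation is deterministic.
#'
#' @param x0 latent array in \[-1, 1\].
#' @param t integer timestep in \[1, T\], or a vector with one entry per row
#'   of a matrix `x0` (per-sample timesteps for training batches).
#' @param eps standard-normal noise, same shape as `x0`.
#' @param schedule a [build_cosine_schedule()] object.
#' @return array of the same shape as `x0`.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  t <- check_t(t, schedule)
  if (!identical(dim(x0), dim(eps)) || length(x0) != length(eps))
    abort_invalid("`x0` and `eps` must have identical shapes")
  ab <- schedule$alpha_bar[t]
  if (length(t) > 1L) {
    if (!is.matrix(x0) || nrow(x0) != length(t))
      abort_invalid("vector `t` requires matrix `x0` with one row per timestep")
    sqrt(ab) * x0 + sqrt(1 - ab) * eps   # recycles down columns
  } else {
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  }
}

#' Closed-form posterior q(x_{t-1} | x_t, x_0)
#'
#' The reverse-time conditional is Gaussian with mean
#' \deqn{\tilde\mu_t = \frac{\sqrt{\bar\alpha_{t-1}}\beta_t}{1-\bar\alpha_t} x_0
#'   + \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}{1-\bar\alpha_t} x_t}
#' and variance \eqn{\tilde\beta_t}. At t = 1 (with
#' \eqn{\bar\alpha_0 := 1}) the mean is \eqn{x_0} and the variance 0: the
#' reverse chain terminates at the data.
#'
#' @inheritParams q_sample
#' @param x_t latent at step t.
#' @return list with `mean` (same shape) and `variance` (scalar, or vector
#'   for vector `t`).
#' @export
posterior_params <- function(x0, x_t, t, schedule) {
  t <- check_t(t, schedule)
  ab      <- schedule$alpha_bar[t]
  ab_prev <- schedule$alpha_bar_prev[t]
  beta    <- schedule$beta[t]
  alpha   <- schedule$alpha[t]
  coef0 <- sqrt(ab_prev) * beta / (1 - ab)
  coeft <- sqrt(alpha) * (1 - ab_prev) / (1 - ab)
  list(mean = coef0 * x0 + coeft * x_t,
       variance = schedule$posterior_variance[t])
}

#' Recover x_0 from a noise estimate
#'
#' Inverts the forward marginal:
#' \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}},
#' clamped to \[-1, 1\].
#'
#' @inheritParams posterior_params
#' @param eps_hat predicted noise, same shape as `x_t`.
#' @param clip clamp the result to \[-1, 1\] (default TRUE).
#' @return latent array of the same shape.
#' @export
predict_x0_from_eps <- function(x_t, t, eps_hat, schedule, clip = TRUE) {
  t <- check_t(t, schedule)
  if (length(x_t) != length(eps_hat))
    abort_invalid("`x_t` and `eps_hat` must have identical shapes")
  ab <- schedule$alpha_bar[t]
  x0 <- (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
  if (clip) clamp(x0) else x0
}

#' Respace a schedule to a shorter sampling subsequence
#'
#' Picks `n` evenly spaced timesteps of the training schedule (always
#' including the final step) and recomputes per-step betas
#' \eqn{\beta'_i = 1 - \bar\alpha_{s_i}/\bar\alpha_{s_{i-1}}} so that the
#' forward marginals at the retained steps are unchanged. Standard practice
#' for fast sampling.
#'
#' @param schedule a training [build_cosine_schedule()] schedule.
#' @param n number of sampling steps (1..T).
#' @return list with `schedule` (a `noise_schedule` of length `n`) and
#'   `timestep_map` (the original timestep each respaced step corresponds to).
#' @export
respace_schedule <- function(schedule, n) {
  check_range(n, "n", 1, schedule$T)
  idx <- unique(round(seq(1, schedule$T, length.out = n)))
  ab <- schedule$alpha_bar[idx]
  ab_prev <- c(1, ab[-length(ab)])
  beta <- 1 - ab / ab_prev
  list(schedule = new_noise_schedule(beta), timestep_map = as.integer(idx))
}
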