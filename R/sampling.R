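# Learned-variance reverse sampling.

#' One reverse diffusion step
#'
#' Draws \eqn{x_{t-1} \sim N(\mu_\theta, \Sigma_\theta)} where the mean is
#' obtained by estimating \eqn{\hat x_0} from the predicted noise and
#' plugging it into the closed-form posterior, and the variance
#' interpolates between the two analytic extremes in log space:
#' \eqn{\log \Sigma_\theta = \hat v \log\beta_t + (1-\hat v)\log\tilde\beta_t}.
#' At t = 1 no noise is added and the mean is returned.
#'
#' @param predictor predictor contract object.
#' @param x_t latent vector/matrix at step t.
#' @param t integer timestep in \[1, T\].
#' @param schedule `noise_schedule`.
#' @param noise optional standard-normal draw of the same shape (supplied
#'   for determinism; drawn from the current RNG stream otherwise).
#' @return latent of the same shape at step t - 1.
#' @export
p_sample_step <- function(predictor, x_t, t, schedule, noise = NULL) {
  t <- check_t(t, schedule)
  pr <- predict_eps_v(predictor, x_t, t)
  if (length(pr$eps_hat) != length(x_t))
    abort_invalid("predictor output shape mismatch",
                  class = "echosynth_contract_error")
  x0_hat <- predict_x0_from_eps(x_t, t, pr$eps_hat, schedule)
  mean <- posterior_params(x0_hat, x_t, t, schedule)$mean
  if (t == 1L) return(mean)
  sigma <- exp(0.5 * interp_logvar(pr$v_hat, t, schedule))
  if (is.null(noise)) noise <- stats::rnorm(length(x_t))
  out <- mean + sigma * noise
  if (!is.null(dim(x_t))) dim(out) <- dim(x_t)
  out
}

#' Unconditional generation
#'
#' Runs the full reverse chain from white noise. Deterministic given
#' `seed`; outputs are clamped to \[-1, 1\].
#'
#' @param predictor predictor contract object.
#' @param schedule `noise_schedule` (respaced or full).
#' @param count number of samples.
#' @param d latent dimensionality; defaults to the predictor's `d`.
#' @param seed integer seed.
#' @return `count` x `d` matrix of latents (0-row matrix for count = 0).
#' @export
generate <- function(predictor, schedule, count, d = NULL, seed = 1L) {
  if (is.null(d)) d <- predictor$d
  if (is.null(d)) abort_invalid("`d` must be given for function predictors")
  count <- as.integer(count)
  if (count == 0L) return(matrix(numeric(0), 0L, d))
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(count * d), count, d)
  for (t in seq(schedule$T, 1L)) {
    noise <- matrix(stats::rnorm(count * d), count, d)
    x <- p_sample_step(predictor, x, t, schedule, noise = noise)
  }
  clamp(x)
}
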