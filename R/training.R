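# Hybrid-loss training with learned variance and importance-sampled
# timesteps.

#' Training configuration
#'
#' Collects the knobs of [train_ddpm()]. The defaults are the package's
#' scaled-down configuration; a full-scale reference configuration
#' (T = 4000, 256 x 256) can be expressed with the same fields but is not
#' exercised by the tests.
#'
#' @param T_steps number of diffusion steps.
#' @param d latent dimensionality (flattened pixel count).
#' @param hidden hidden-layer widths of the MLP predictor.
#' @param te_dim time-embedding width.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param n_steps number of optimisation steps.
#' @param vlb_weight weight of the variational (learned-variance) term.
#' @param is_warmup per-timestep loss count required before importance
#'   sampling switches on (uniform until then).
#' @param ema_decay exponential-moving-average decay for the returned
#'   weights (0 disables EMA); standard stabiliser for diffusion training.
#' @param lr_decay if TRUE the learning rate decays linearly to zero over
#'   the run.
#' @param stride_range inclusive range of the random frame stride used when
#'   subsampling cine sequences for training data.
#' @param seed master seed for initialisation and batch sampling.
#' @return a list of class `training_config`.
#' @export
training_config <- function(T_steps = 1000L, d, hidden = c(96, 96),
                            te_dim = 16L, batch_size = 64L, lr = 1e-3,
                            n_steps = 2000L, vlb_weight = 0.001,
                            is_warmup = 10L, stride_range = c(8L, 12L),
                            ema_decay = 0.999, lr_decay = TRUE,
                            seed = 1L) {
  if (vlb_weight < 0) abort_invalid("`vlb_weight` must be >= 0")
  if (stride_range[1] < 1 || stride_range[1] > stride_range[2])
    abort_invalid("`stride_range` must satisfy 1 <= low <= high")
  structure(as.list(environment()), class = "training_config")
}

# log-variance of the predicted reverse Gaussian:
# log Sigma = v * log(beta_t) + (1 - v) * log(beta_tilde_t)
interp_logvar <- function(v_hat, t, schedule) {
  lb <- log(schedule$beta[t])
  lbt <- log(schedule$posterior_variance[t])
  v_hat * lb + (1 - v_hat) * lbt
}

# KL( N(mu1, var1) || N(mu2, var2) ), elementwise
gaussian_kl <- function(mu1, var1, mu2, var2) {
  0.5 * (log(var2 / var1) + (var1 + (mu1 - mu2)^2) / var2 - 1)
}

#' Hybrid training loss
#'
#' Mean squared error between the true and predicted noise, plus
#' `vlb_weight` times the per-timestep KL divergence between the
#' closed-form posterior q(x_\{t-1\} | x_t, x_0) and the predicted reverse
#' Gaussian. In the KL term the predicted mean is treated as a constant
#' (gradient flows to the variance only); at t = 1 the posterior variance
#' is zero and the term is dropped.
#'
#' @param predictor predictor contract object.
#' @param x0 n x d matrix of clean latents.
#' @param t length-n integer timesteps.
#' @param eps n x d matrix of standard-normal noise.
#' @param schedule `noise_schedule`.
#' @param vlb_weight non-negative scalar.
#' @param weights optional length-n importance weights (default 1).
#' @return list with `loss`, `mse`, `vlb` scalars and `per_sample` loss.
#' @export
hybrid_loss <- function(predictor, x0, t, eps, schedule, vlb_weight = 0.001,
                        weights = NULL) {
  if (!is.matrix(x0) || nrow(x0) < 1L) abort_invalid("`x0` must be a non-empty matrix")
  if (vlb_weight < 0) abort_invalid("`vlb_weight` must be >= 0")
  t <- check_t(t, schedule)
  if (length(t) == 1L) t <- rep(t, nrow(x0))
  if (is.null(weights)) weights <- rep(1, nrow(x0))
  x_t <- q_sample(x0, t, eps, schedule)
  pr <- predict_eps_v(predictor, x_t, t)
  per_mse <- rowMeans((pr$eps_hat - eps)^2)
  per_vlb <- vlb_term(pr, x0, x_t, t, schedule)$per_sample
  per_sample <- per_mse + vlb_weight * per_vlb
  list(loss = mean(weights * per_sample),
       mse = mean(weights * per_mse),
       vlb = mean(weights * per_vlb),
       per_sample = per_sample)
}

# Variational term and the quantities needed for its gradient.
vlb_term <- function(pr, x0, x_t, t, schedule) {
  q <- posterior_params(x0, x_t, t, schedule)
  x0_hat <- predict_x0_from_eps(x_t, t, pr$eps_hat, schedule)
  p_mean <- posterior_params(x0_hat, x_t, t, schedule)$mean  # detached in KL
  logvar <- interp_logvar(pr$v_hat, t, schedule)
  var_p <- exp(logvar)
  qv <- q$variance                       # per-sample scalar, recycled
  kl <- 0.5 * (logvar - log(qv)) + (qv + (q$mean - p_mean)^2) / (2 * var_p) - 0.5
  kl[t == 1L, ] <- 0                     # posterior variance 0: term dropped
  list(per_sample = rowMeans(kl), kl = kl, q = q, p_mean = p_mean,
       logvar = logvar, var_p = var_p)
}

#' Loss-aware timestep sampler
#'
#' Importance sampling over timesteps: t is drawn with probability
#' proportional to the square root of the running mean of its last
#' `history` squared losses, and the drawn sample carries weight
#' 1/(T p_t). Until every timestep has accumulated at least `warmup`
#' recorded losses, sampling is uniform with unit weights.
#'
#' @param T_steps schedule length.
#' @param history per-timestep history length (default 10).
#' @param warmup recorded-loss count before switching on (default 10).
#' @return an environment with `sample_t(n)` and `record(t, loss)` closures.
#' @export
importance_sampler <- function(T_steps, history = 10L, warmup = 10L) {
  hist <- matrix(NA_real_, T_steps, history)
  count <- integer(T_steps)
  ptr <- integer(T_steps)
  self <- new.env(parent = emptyenv())
  self$record <- function(t, loss) {
    for (i in seq_along(t)) {
      ti <- t[i]
      ptr[ti] <<- (ptr[ti] %% history) + 1L
      hist[ti, ptr[ti]] <<- loss[i]
      count[ti] <<- count[ti] + 1L
    }
    invisible(NULL)
  }
  self$probs <- function() {
    if (any(count < warmup)) return(rep(1 / T_steps, T_steps))
    p <- sqrt(rowMeans(hist^2, na.rm = TRUE))
    p / sum(p)
  }
  self$sample_t <- function(n = 1L) {
    p <- self$probs()
    t <- sample.int(T_steps, n, replace = TRUE, prob = p)
    list(t = t, weight = 1 / (T_steps * p[t]))
  }
  self$warmed_up <- function() all(count >= warmup)
  self
}

#' Train an MLP diffusion predictor
#'
#' Minimises the hybrid loss over a dataset of flattened latents with Adam,
#' drawing timesteps from an importance sampler. Deterministic for a fixed
#' config seed.
#'
#' @param dataset n x d matrix of latents in \[-1,1\], or a list of
#'   equal-shape arrays which are flattened row-wise.
#' @param config a [training_config()].
#' @param schedule optional `noise_schedule`; defaults to the cosine
#'   schedule of length `config$T_steps`.
#' @return a trained `mlp_predictor` with attribute `training_log`
#'   (data.frame: step, loss, mse, vlb).
#' @export
train_ddpm <- function(dataset, config, schedule = NULL) {
  X <- as_latent_matrix(dataset)
  if (nrow(X) < 1L) abort_invalid("`dataset` must be non-empty")
  if (is.null(schedule)) schedule <- build_cosine_schedule(config$T_steps)
  d <- ncol(X)
  if (!is.null(config$d) && config$d != d)
    abort_invalid(sprintf("config$d = %d but dataset has %d features", config$d, d))
  set.seed(derive_seed(config$seed, "train"))
  p <- new_mlp_predictor(d, config$hidden, config$te_dim,
                         schedule$T, seed = derive_seed(config$seed, "init"))
  sampler <- importance_sampler(schedule$T, warmup = config$is_warmup)
  mstate <- lapply(p$W, function(w) array(0, dim(w)))
  vstate <- mstate
  mb <- lapply(p$b, function(bb) numeric(length(bb)))
  vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  ema_W <- p$W; ema_b <- p$b; ed <- config$ema_decay
  log_rows <- vector("list", config$n_steps)
  for (step in seq_len(config$n_steps)) {
    idx <- sample.int(nrow(X), min(config$batch_size, nrow(X)), replace = TRUE)
    x0 <- X[idx, , drop = FALSE]
    ts <- sampler$sample_t(nrow(x0))
    eps <- matrix(stats::rnorm(length(x0)), nrow(x0), d)
    x_t <- q_sample(x0, ts$t, eps, schedule)
    fw <- mlp_forward(p, x_t, ts$t, keep_cache = TRUE)
    pr <- list(eps_hat = fw$eps_hat, v_hat = fw$v_hat)
    vt <- vlb_term(pr, x0, x_t, ts$t, schedule)
    per_mse <- rowMeans((fw$eps_hat - eps)^2)
    per_sample <- per_mse + config$vlb_weight * vt$per_sample
    w <- ts$weight
    n <- nrow(x0)
    # d(loss)/d(eps_hat): weighted MSE term only (KL mean is detached)
    d_eps <- (2 / (n * d)) * w * (fw$eps_hat - eps)
    # d(loss)/d(v_raw) through log Sigma = v log(beta) + (1-v) log(beta_tilde)
    dkl_dlogvar <- 0.5 - (vt$q$variance + (vt$q$mean - vt$p_mean)^2) / (2 * vt$var_p)
    dlogvar_dv <- log(schedule$beta[ts$t]) - log(schedule$posterior_variance[ts$t])
    d_v <- (config$vlb_weight / (n * d)) * w * dkl_dlogvar * dlogvar_dv
    d_v[ts$t == 1L, ] <- 0
    d_vraw <- d_v * fw$v_hat * (1 - fw$v_hat)
    g <- mlp_backward(p, fw, d_eps, d_vraw)
    sc <- sqrt(1 - b2^step) / (1 - b1^step)
    lr_t <- if (isTRUE(config$lr_decay))
      config$lr * (1 - (step - 1) / config$n_steps) else config$lr
    for (i in seq_along(p$W)) {
      mstate[[i]] <- b1 * mstate[[i]] + (1 - b1) * g$W[[i]]
      vstate[[i]] <- b2 * vstate[[i]] + (1 - b2) * g$W[[i]]^2
      p$W[[i]] <- p$W[[i]] - lr_t * sc * mstate[[i]] / (sqrt(vstate[[i]]) + eps_adam)
      mb[[i]] <- b1 * mb[[i]] + (1 - b1) * g$b[[i]]
      vb[[i]] <- b2 * vb[[i]] + (1 - b2) * g$b[[i]]^2
      p$b[[i]] <- p$b[[i]] - lr_t * sc * mb[[i]] / (sqrt(vb[[i]]) + eps_adam)
      if (ed > 0) {
        ema_W[[i]] <- ed * ema_W[[i]] + (1 - ed) * p$W[[i]]
        ema_b[[i]] <- ed * ema_b[[i]] + (1 - ed) * p$b[[i]]
      }
    }
    sampler$record(ts$t, per_sample)
    log_rows[[step]] <- c(step, mean(w * per_sample), mean(w * per_mse),
                          mean(w * vt$per_sample))
  }
  if (ed > 0) { p$W <- ema_W; p$b <- ema_b }
  log_df <- as.data.frame(do.call(rbind, log_rows))
  names(log_df) <- c("step", "loss", "mse", "vlb")
  attr(p, "training_log") <- log_df
  p
}

as_latent_matrix <- function(dataset) {
  if (is.matrix(dataset)) return(dataset)
  if (is.list(dataset)) {
    if (length(dataset) == 0L) abort_invalid("`dataset` must be non-empty")
    shp <- dim(dataset[[1]])
    lens <- vapply(dataset, length, 0L)
    if (any(lens != length(dataset[[1]])))
      abort_invalid("all dataset samples must have the same shape")
    for (s in dataset)
      if (!is.null(shp) && !identical(dim(s), shp))
        abort_invalid("all dataset samples must have the same shape")
    return(do.call(rbind, lapply(dataset, as.numeric)))
  }
  abort_invalid("`dataset` must be a matrix or a list of arrays")
}
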