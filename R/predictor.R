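# Diffusion predictor contract and a small fully-connected implementation.
#
# A predictor maps (latent, timestep) -> (eps_hat, v_hat): the estimated
# noise and the variance-interpolation coefficient in [0,1] used for the
# learned-variance reverse step. The full-scale reference model is a U-Net;
# this package ships a compact multilayer perceptron with sinusoidal time
# embeddings, which is sufficient for the scaled-down phantom experiments
# and for the analytic toy problems used in the tests.

#' Evaluate a diffusion predictor
#'
#' Generic dispatch for the predictor contract. `x` may be a length-d
#' latent vector or an n x d matrix of latents (one per row); `t` is a
#' single timestep or a vector of n timesteps. The return value is a list
#' with `eps_hat` (same shape as `x`) and `v_hat` (same shape, values in
#' \[0,1\]).
#'
#' A plain R function of `(x, t)` returning such a list is accepted
#' wherever a predictor is expected, which makes stub predictors for
#' testing trivial to write.
#'
#' @param predictor an `mlp_predictor` or a function.
#' @param x latent vector or matrix.
#' @param t integer timestep(s).
#' @return list with elements `eps_hat`, `v_hat`.
#' @export
predict_eps_v <- function(predictor, x, t) UseMethod("predict_eps_v")

#' @export
predict_eps_v.function <- function(predictor, x, t) {
  out <- predictor(x, t)
  if (!is.list(out) || is.null(out$eps_hat) || is.null(out$v_hat) ||
      length(out$eps_hat) != length(x) || length(out$v_hat) != length(x))
    abort_invalid("predictor output shape mismatch",
                  class = "echosynth_contract_error")
  out
}

#' @export
predict_eps_v.mlp_predictor <- function(predictor, x, t) {
  vec_in <- !is.matrix(x)
  X <- if (vec_in) matrix(x, nrow = 1L) else x
  if (ncol(X) != predictor$d)
    abort_invalid(sprintf("latent has %d features, predictor expects %d",
                          ncol(X), predictor$d),
                  class = "echosynth_contract_error")
  tt <- if (length(t) == 1L) rep(as.integer(t), nrow(X)) else as.integer(t)
  fw <- mlp_forward(predictor, X, tt)
  eps_hat <- fw$eps_hat; v_hat <- fw$v_hat
  if (vec_in) { eps_hat <- drop(eps_hat); v_hat <- drop(v_hat) }
  if (is.matrix(x)) { dim(eps_hat) <- dim(x); dim(v_hat) <- dim(x) }
  list(eps_hat = eps_hat, v_hat = v_hat)
}

#' Create an untrained MLP diffusion predictor
#'
#' Architecture: input = latent (d values) concatenated with a sinusoidal
#' timestep embedding; `hidden` tanh layers; a linear head of 2d outputs,
#' split into the noise estimate (first d, linear) and the variance
#' interpolation coefficient (last d, through a sigmoid).
#'
#' @param d latent dimensionality (number of pixels).
#' @param hidden integer vector of hidden-layer widths.
#' @param te_dim time-embedding dimensionality (even).
#' @param T_steps schedule length (used to scale the embedding frequencies).
#' @param seed integer seed for the initialisation.
#' @return object of class `mlp_predictor`.
#' @export
new_mlp_predictor <- function(d, hidden = c(96, 96), te_dim = 16L,
                              T_steps = 1000L, seed = 1L) {
  if (te_dim %% 2L != 0L) abort_invalid("`te_dim` must be even")
  set.seed(as.integer(seed))
  sizes <- c(d + te_dim, hidden, 2L * d)
  W <- vector("list", length(sizes) - 1L); b <- W
  for (i in seq_along(W)) {
    sd_i <- sqrt(2 / (sizes[i] + sizes[i + 1L]))
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], sd = sd_i),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- numeric(sizes[i + 1L])
  }
  structure(list(d = as.integer(d), hidden = as.integer(hidden),
                 te_dim = as.integer(te_dim), T_steps = as.integer(T_steps),
                 W = W, b = b,
                 n_params = sum(vapply(W, length, 0L)) + sum(lengths(b)),
                 version = 1L),
            class = "mlp_predictor")
}

#' @export
print.mlp_predictor <- function(x, ...) {
  cat(sprintf("<mlp_predictor> d = %d, hidden = [%s], %d parameters\n",
              x$d, paste(x$hidden, collapse = ", "), x$n_params))
  invisible(x)
}

time_embedding <- function(t, te_dim, T_steps) {
  half <- te_dim / 2
  freqs <- exp(-log(1000) * (0:(half - 1)) / max(half - 1, 1))
  ang <- outer(t / T_steps * 2 * pi, freqs)   # n x half
  cbind(sin(ang), cos(ang))
}

# Forward pass with caches for backprop. X: n x d, t: length-n integer.
mlp_forward <- function(p, X, t, keep_cache = FALSE) {
  A <- cbind(X, time_embedding(t, p$te_dim, p$T_steps))
  nl <- length(p$W)
  cache <- if (keep_cache) vector("list", nl) else NULL
  for (i in seq_len(nl - 1L)) {
    if (keep_cache) cache[[i]] <- A
    A <- tanh(sweep(A %*% p$W[[i]], 2, p$b[[i]], "+"))
  }
  if (keep_cache) cache[[nl]] <- A
  out <- sweep(A %*% p$W[[nl]], 2, p$b[[nl]], "+")
  d <- p$d
  eps_hat <- out[, seq_len(d), drop = FALSE]
  v_raw <- out[, d + seq_len(d), drop = FALSE]
  v_hat <- 1 / (1 + exp(-v_raw))
  list(eps_hat = eps_hat, v_hat = v_hat, v_raw = v_raw, cache = cache)
}

# Backprop: d_eps, d_vraw are gradients of the loss wrt eps_hat and the
# pre-sigmoid variance output. Returns gradients for W and b.
mlp_backward <- function(p, fw, d_eps, d_vraw) {
  nl <- length(p$W)
  dOut <- cbind(d_eps, d_vraw)
  gW <- vector("list", nl); gb <- gW
  dA <- dOut
  for (i in rev(seq_len(nl))) {
    A_in <- fw$cache[[i]]
    gW[[i]] <- crossprod(A_in, dA)
    gb[[i]] <- colSums(dA)
    if (i > 1L) {
      dH <- dA %*% t(p$W[[i]])
      dA <- dH * (1 - fw$cache[[i]]^2)  # cache[[i]] holds tanh activations fed to layer i
    }
  }
  list(W = gW, b = gb)
}

#' Save / load a predictor checkpoint
#'
#' A checkpoint is a single versioned archive holding the predictor
#' parameters, the training schedule and the training configuration.
#' Reloading restores bit-identical predictions.
#'
#' @param predictor an `mlp_predictor`.
#' @param schedule the training `noise_schedule`.
#' @param config the training configuration list.
#' @param path file path for the archive.
#' @return `path`, invisibly (`save_checkpoint`); a list with `predictor`,
#'   `schedule`, `config` (`load_checkpoint`).
#' @export
save_checkpoint <- function(predictor, schedule, config, path) {
  saveRDS(list(format = "echosynth-checkpoint", version = 1L,
               predictor = predictor, schedule = schedule, config = config),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "echosynth-checkpoint"))
    abort_invalid("not an echosynth checkpoint", class = "echosynth_load_error")
  ck[c("predictor", "schedule", "config")]
}
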