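# Hybrid loss, importance sampling, training behaviour.

test_that("hybrid loss is zero for a perfect stub and reduces to MSE", {
  s <- build_cosine_schedule(40)
  set.seed(3)
  x0 <- matrix(runif(20, -0.5, 0.5), 4, 5)
  eps <- matrix(rnorm(20), 4, 5)
  tt <- c(5L, 10L, 20L, 40L)

  # a stub that returns the true noise and the posterior variance (v = 0)
  perfect <- local({
    eps_true <- eps
    function(x, t) list(eps_hat = eps_true, v_hat = eps_true * 0)
  })
  l <- hybrid_loss(perfect, x0, tt, eps, s, vlb_weight = 0.001)
  expect_lt(l$loss, 1e-10)

  # vlb_weight = 0: plain MSE on the noise
  f <- function(x, t) list(eps_hat = x * 0, v_hat = x * 0 + 0.5)
  l0 <- hybrid_loss(f, x0, tt, eps, s, vlb_weight = 0)
  expect_equal(l0$loss, mean(rowMeans(eps^2)))
  expect_gte(l0$loss, 0)

  expect_error(hybrid_loss(f, matrix(numeric(0), 0, 5), integer(0),
                           matrix(numeric(0), 0, 5), s),
               class = "echosynth_invalid_argument")
  expect_error(hybrid_loss(f, x0, tt, eps, s, vlb_weight = -1),
               class = "echosynth_invalid_argument")
})

test_that("Gaussian KL term matches the closed form", {
  # KL(N(mu1, v1) || N(mu2, v2)) for explicit 1-D numbers
  kl <- echosynth:::gaussian_kl(0.3, 0.5, -0.1, 1.2)
  oracle <- log(sqrt(1.2) / sqrt(0.5)) + (0.5 + (0.3 + 0.1)^2) / (2 * 1.2) - 0.5
  expect_equal(kl, oracle, tolerance = 1e-12)
  expect_equal(echosynth:::gaussian_kl(0.4, 0.7, 0.4, 0.7), 0)
  expect_gte(echosynth:::gaussian_kl(1, 2, 3, 4), 0)
})

test_that("importance sampler: warm-up uniform, then square-root law", {
  T_steps <- 5L
  is1 <- importance_sampler(T_steps, warmup = 10L)
  # warm-up: exactly uniform probabilities
  expect_equal(is1$probs(), rep(1 / T_steps, T_steps))
  # all-equal histories: uniform within Monte-Carlo error
  for (t in 1:T_steps) is1$record(rep(t, 10), rep(2, 10))
  expect_equal(is1$probs(), rep(1 / T_steps, T_steps))
  set.seed(4)
  draws <- is1$sample_t(1e5)
  freq <- tabulate(draws$t, T_steps) / 1e5
  expect_true(all(abs(freq - 0.2) < 0.01))
  expect_true(all(draws$weight == 1))

  # p_t is proportional to sqrt(E[L_t^2]): a timestep whose recorded loss
  # is 10x larger is sampled 10x as often (and 100x loss -> 100x, since
  # the loss enters squared under the square root)
  is2 <- importance_sampler(T_steps, warmup = 10L)
  for (t in 1:T_steps) is2$record(rep(t, 10), rep(if (t == 3) 10 else 1, 10))
  p <- is2$probs()
  expect_equal(p[3] / p[1], 10, tolerance = 1e-9)
  set.seed(5)
  d2 <- is2$sample_t(1e5)
  f2 <- tabulate(d2$t, T_steps) / 1e5
  expect_equal(f2[3] / f2[1], 10, tolerance = 0.6)
  # returned weights invert the sampling probability
  expect_equal(sort(unique(d2$weight)), sort(unique(1 / (T_steps * p))),
               tolerance = 1e-9)
})

test_that("training decreases the loss on phantom crops and is serializable", {
  crops <- lapply(1:8, function(i) {
    s <- phantom_small(seed = i, size = 16L)
    image_to_latent(s$image)
  })
  cfg <- training_config(T_steps = 40L, d = 256L, hidden = 32L,
                         batch_size = 8L, n_steps = 400L, seed = 2L)
  p <- train_ddpm(crops, cfg)
  lg <- attr(p, "training_log")
  expect_lt(mean(tail(lg$loss, 50)), mean(head(lg$loss, 50)))

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, build_cosine_schedule(40L), cfg, path)
  probe <- matrix(runif(256, -1, 1), 1, 256)
  expect_identical(predict_eps_v(load_checkpoint(path)$predictor, probe, 9L),
                   predict_eps_v(p, probe, 9L))

  # inconsistent shapes rejected
  bad <- c(crops, list(matrix(0, 4, 4)))
  expect_error(train_ddpm(bad, cfg), class = "echosynth_invalid_argument")
  expect_error(train_ddpm(list(), cfg), class = "echosynth_invalid_argument")
})
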