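# Noise schedule and closed-form forward/posterior quantities.

test_that("cosine schedule satisfies its invariants", {
  expect_error(build_cosine_schedule(0), class = "echosynth_invalid_argument")
  expect_error(build_cosine_schedule(-3), class = "echosynth_invalid_argument")

  s1 <- build_cosine_schedule(1)
  expect_length(s1$beta, 1)
  expect_gt(s1$beta, 0); expect_lt(s1$beta, 1)
  expect_equal(s1$alpha_bar, 1 - s1$beta)

  for (T_steps in c(10, 250, 1000)) {
    s <- build_cosine_schedule(T_steps)
    expect_true(all(s$beta > 0 & s$beta < 1))
    expect_true(all(s$beta <= 0.999))
    expect_true(all(diff(s$alpha_bar) < 0))
    # independent cumulative-product oracle
    oracle <- Reduce(function(a, b) a * b, 1 - s$beta, accumulate = TRUE)
    expect_lt(max(abs(s$alpha_bar - oracle)), 1e-10)
  }

  s4000 <- build_cosine_schedule(4000)
  expect_lt(s4000$alpha_bar[4000], 1e-3)
})

test_that("q_sample matches its closed form and limits", {
  s <- build_cosine_schedule(100)
  x0 <- matrix(runif(12, -1, 1), 3, 4)
  z <- matrix(0, 3, 4)
  for (t in c(1, 37, 100))
    expect_equal(q_sample(x0, t, z, s), sqrt(s$alpha_bar[t]) * x0)

  # at t = T of a long chain the latent is essentially the noise
  sl <- build_cosine_schedule(4000)
  eps <- matrix(rnorm(12), 3, 4)
  expect_lt(max(abs(q_sample(x0, 4000, eps, sl) - eps)), 0.05)

  expect_error(q_sample(x0, 0, z, s), class = "echosynth_range_error")
  expect_error(q_sample(x0, 101, z, s), class = "echosynth_range_error")
})

test_that("q_sample moments match the marginal (Monte-Carlo oracle)", {
  s <- build_cosine_schedule(100)
  t <- 50L
  n <- 1e5
  set.seed(101)
  draws <- q_sample(matrix(0.5, n, 1), rep(t, n), matrix(rnorm(n), n, 1), s)
  ab <- s$alpha_bar[t]
  se_mean <- sqrt(1 - ab) / sqrt(n)
  expect_lt(abs(mean(draws) - sqrt(ab) * 0.5), 3 * se_mean)
  se_var <- (1 - ab) * sqrt(2 / (n - 1))
  expect_lt(abs(var(as.numeric(draws)) - (1 - ab)), 3 * se_var)
})

test_that("posterior parameters match an independent re-derivation", {
  s <- build_cosine_schedule(60)
  x0 <- matrix(runif(8, -1, 1), 2, 4)
  xt <- matrix(runif(8, -1, 1), 2, 4)

  # t = 1: reverse chain terminates at the data
  p1 <- posterior_params(x0, xt, 1, s)
  expect_equal(p1$mean, x0)
  expect_equal(p1$variance, 0)
  expect_error(posterior_params(x0, xt, 0, s), class = "echosynth_range_error")

  # independent symbolic oracle evaluated numerically
  for (t in c(2, 17, 60)) {
    ab <- prod(1 - s$beta[1:t]); abp <- prod(1 - s$beta[seq_len(t - 1)])
    mean_o <- (sqrt(abp) * s$beta[t] / (1 - ab)) * x0 +
      (sqrt(1 - s$beta[t]) * (1 - abp) / (1 - ab)) * xt
    var_o <- (1 - abp) / (1 - ab) * s$beta[t]
    p <- posterior_params(x0, xt, t, s)
    expect_equal(p$mean, mean_o, tolerance = 1e-12)
    expect_equal(p$variance, var_o, tolerance = 1e-12)
  }

  # noiseless trajectory: posterior mean collapses onto it
  t <- 30L
  xt0 <- q_sample(x0, t, matrix(0, 2, 4), s)
  m <- posterior_params(x0, xt0, t, s)$mean
  expect_equal(m, q_sample(x0, t - 1L, matrix(0, 2, 4), s), tolerance = 1e-12)
})

test_that("marginalizing the posterior over x_t reproduces q(x_{t-1}|x0)", {
  # scalar Monte-Carlo moment matching
  s <- build_cosine_schedule(40)
  t <- 25L; x0 <- 0.3; n <- 1e5
  set.seed(77)
  xt <- q_sample(matrix(x0, n, 1), rep(t, n), matrix(rnorm(n), n, 1), s)
  pp <- posterior_params(matrix(x0, n, 1), xt, t, s)
  xtm1 <- pp$mean + sqrt(pp$variance) * rnorm(n)
  abm1 <- s$alpha_bar_prev[t]
  expect_lt(abs(mean(xtm1) - sqrt(abm1) * x0), 3 * sqrt(1 - abm1) / sqrt(n))
  expect_lt(abs(var(as.numeric(xtm1)) - (1 - abm1)),
            3 * (1 - abm1) * sqrt(2 / (n - 1)))
})

test_that("predict_x0_from_eps inverts the forward marginal", {
  s <- build_cosine_schedule(80)
  x0 <- matrix(runif(10, -0.9, 0.9), 2, 5)
  eps <- matrix(rnorm(10), 2, 5)
  for (t in c(3, 40, 80)) {
    xt <- q_sample(x0, t, eps, s)
    expect_equal(predict_x0_from_eps(xt, t, eps, s), x0, tolerance = 1e-9)
  }
  expect_equal(predict_x0_from_eps(matrix(0, 2, 2), 10, matrix(0, 2, 2), s),
               matrix(0, 2, 2))
  # direct algebra oracle without clipping
  xt <- matrix(runif(10, -1, 1), 2, 5)
  eh <- matrix(rnorm(10), 2, 5)
  t <- 55L
  ab <- s$alpha_bar[t]
  expect_equal(predict_x0_from_eps(xt, t, eh, s, clip = FALSE),
               (xt - sqrt(1 - ab) * eh) / sqrt(ab))
})

test_that("respaced schedules preserve the retained forward marginals", {
  s <- build_cosine_schedule(1000)
  rs <- respace_schedule(s, 50)
  expect_equal(rs$schedule$alpha_bar,
               s$alpha_bar[rs$timestep_map], tolerance = 1e-12)
  expect_equal(rs$timestep_map[length(rs$timestep_map)], 1000L)
  expect_true(all(diff(rs$schedule$alpha_bar) < 0))
})
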