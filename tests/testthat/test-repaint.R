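# RePaint inference: jump schedules, exact preservation, conditioning.

test_that("jump schedule: plain descent, hand-enumerated case, net descent", {
  expect_identical(build_jump_schedule(6, 2, 0), seq.int(6L, 1L))

  # T = 4, jump_length = 2, n_resample = 1, enumerable by hand:
  # block [4,3], resample loop up(3,4)/down(4,3), block [2,1], loop up(1,2)/down(2,1)
  expect_identical(build_jump_schedule(4, 2, 1),
                   c(4L, 3L, -3L, -4L, 4L, 3L, 2L, 1L, -1L, -2L, 2L, 1L))

  # counting invariant: every forward jump is matched by an extra reverse
  # step, so reverse steps minus forward steps equals T
  for (cfg in list(c(10, 3, 2), c(25, 10, 10), c(7, 7, 1))) {
    js <- build_jump_schedule(cfg[1], cfg[2], cfg[3])
    expect_equal(sum(js > 0) - sum(js < 0), cfg[1])
    # stated length for a full schedule
    if (cfg[1] %% cfg[2] == 0) {
      B <- cfg[1] / cfg[2]
      expect_length(js, cfg[1] + 2 * cfg[2] * cfg[3] * B)
    }
  }
  expect_error(build_jump_schedule(10, 0, 1), class = "echosynth_invalid_argument")
})

test_that("kept region is preserved bit-identically for any predictor", {
  s <- build_cosine_schedule(15)
  p <- new_mlp_predictor(12, hidden = 8, te_dim = 4, T_steps = 15, seed = 2)
  set.seed(21)
  for (rep_i in 1:5) {
    known <- matrix(runif(12, -1, 1), 1, 12)
    keep <- matrix(rbinom(12, 1, 0.5), 1, 12)
    out <- repaint_latent(p, s, known, keep, jump_length = 3, n_resample = 1,
                          seed = rep_i)
    expect_identical(out[keep == 1], known[keep == 1])
  }
  # all-ones mask: output equals input everywhere
  known <- matrix(runif(12, -1, 1), 1, 12)
  ones <- matrix(1, 1, 12)
  expect_identical(repaint_latent(p, s, known, ones, seed = 3),
                   known)
  # image-level wrapper preserves the kept pixels of a [0,1] image
  img <- matrix(runif(64), 8, 8)
  keepm <- matrix(rbinom(64, 1, 0.6), 8, 8)
  pi8 <- new_mlp_predictor(64, hidden = 8, te_dim = 4, T_steps = 15, seed = 4)
  out <- repaint(pi8, s, img, keepm, jump_length = 3, n_resample = 1, seed = 9)
  expect_identical(out[keepm == 1], img[keepm == 1])
  expect_true(all(out >= 0 & out <= 1))
  expect_error(repaint(pi8, s, img, keepm[1:4, ]),
               class = "echosynth_invalid_argument")
})

test_that("repaint is deterministic and resampling leaves the kept region alone", {
  s <- build_cosine_schedule(15)
  p <- new_mlp_predictor(10, hidden = 8, te_dim = 4, T_steps = 15, seed = 6)
  known <- matrix(runif(10, -1, 1), 1, 10)
  keep <- matrix(rep(c(1, 0), 5), 1, 10)
  a <- repaint_latent(p, s, known, keep, 3, 1, seed = 5)
  expect_identical(a, repaint_latent(p, s, known, keep, 3, 1, seed = 5))
  b <- repaint_latent(p, s, known, keep, 3, 4, seed = 5)
  expect_identical(a[keep == 1], b[keep == 1])
  # per-step known-noising variant keeps the same guarantee
  c_ <- repaint_latent(p, s, known, keep, 3, 1, seed = 5,
                       noise_known = "per-step")
  expect_identical(c_[keep == 1], known[keep == 1])
})

test_that("repainted values track a positively correlated conditioner", {
  # conditional coherence on the trained toy model: larger kept pixel 1
  # shifts the repainted pixel 2 upward (rho > 0)
  m <- toy_model_t50()
  n <- 400
  keep <- matrix(rep(c(1, 0), each = n), n, 2)
  lo <- repaint_latent(m$predictor, m$schedule,
                       matrix(rep(c(-0.2, 0), each = n), n, 2), keep,
                       jump_length = 1, n_resample = 5, seed = 31)
  hi <- repaint_latent(m$predictor, m$schedule,
                       matrix(rep(c(0.6, 0), each = n), n, 2), keep,
                       jump_length = 1, n_resample = 5, seed = 31)
  expect_gt(mean(hi[, 2]), mean(lo[, 2]))
})
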