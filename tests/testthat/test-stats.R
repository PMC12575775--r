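# Agreement and testing statistics against enumeration oracles.

test_that("Bland-Altman: hand case, equivariance, errors", {
  r <- c(10, 20, 30)
  expect_equal(bland_altman(r, r)$bias, 0)
  expect_equal(bland_altman(r, r)$loa_low, 0)
  ba <- bland_altman(c(0, 0), c(1, -1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  set.seed(3)
  est <- rnorm(10); ref <- rnorm(10)
  b0 <- bland_altman(ref, est)
  b1 <- bland_altman(ref, est + 5)
  expect_equal(b1$bias, b0$bias + 5)
  expect_equal(b1$loa_high - b1$loa_low, b0$loa_high - b0$loa_low)
  expect_lte(b0$loa_low, b0$bias); expect_gte(b0$loa_high, b0$bias)
  expect_error(bland_altman(1, 1), class = "echosynth_invalid_argument")
  expect_error(bland_altman(1:3, 1:4), class = "echosynth_invalid_argument")
})

# exhaustive sign-flip oracle for the signed-rank test: two-sided p as the
# null probability of a rank sum at least as extreme as observed
signrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  mean(abs(Vs - mu) >= abs(V - mu) - 1e-9)
}

test_that("Wilcoxon signed-rank: exact cases, enumeration oracle, Bonferroni", {
  # n = 5 one-signed differences: exact two-sided p = 2/32
  w <- wilcoxon_bonferroni(c(1, 2, 3, 4, 5), c(0.5, 1.4, 2.3, 3.2, 4.1))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$statistic, 15)
  expect_identical(w$method, "exact")

  # perfectly antisymmetric differences: statistic at the null center, p = 1
  w2 <- wilcoxon_bonferroni(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(w2$p_value, 1)

  # random paired data vs the exhaustive sign-assignment oracle
  set.seed(31)
  for (i in 1:5) {
    a <- round(rnorm(8), 2); b <- round(rnorm(8), 2)
    d <- a - b
    if (any(d == 0) || any(duplicated(abs(d[d != 0])))) next
    w3 <- wilcoxon_bonferroni(a, b)
    expect_equal(w3$p_value, signrank_enum_p(d), tolerance = 1e-9)
  }

  # Bonferroni adjustment and significance flag
  wp <- wilcoxon_bonferroni(c(1, 2, 3, 4, 5), c(0.5, 1.4, 2.3, 3.2, 4.1), m = 6)
  expect_equal(wp$p_adjusted, min(1, 6 * wp$p_value))
  expect_false(wp$significant)  # 0.375 > 0.05

  expect_error(wilcoxon_bonferroni(1:4, 1:4),
               class = "echosynth_undefined_test")
})

test_that("Cohen's kappa: printed table, constants, Monte-Carlo null", {
  # 2x2 table with counts (a,b,c,d) = (20,5,10,15): p_o = 0.7, p_e = 0.5
  r1 <- rep(c("A", "A", "B", "B"), c(20, 5, 10, 15))
  r2 <- rep(c("A", "B", "A", "B"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(r1, r2), 0.4)
  expect_equal(cohens_kappa(r1, r1), 1)
  # both constant and equal -> 1; constant but different -> 0
  expect_equal(cohens_kappa(rep("A", 5), rep("A", 5)), 1)
  expect_equal(cohens_kappa(rep("A", 5), rep("B", 5)), 0)
  # independent uniform ratings: kappa ~ 0
  set.seed(8)
  x <- sample(c("A", "B"), 1e4, TRUE); y <- sample(c("A", "B"), 1e4, TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 0.05)

  # group averages: within = mean over distinct pairs, between = cross pairs
  g1 <- list(r1, r2)
  expect_equal(average_pairwise_kappa(g1), cohens_kappa(r1, r2))
  g2 <- list(r1)
  expect_equal(average_pairwise_kappa(g1, g2),
               mean(c(cohens_kappa(r1, r1), cohens_kappa(r2, r1))))
  expect_error(average_pairwise_kappa(list(r1)),
               class = "echosynth_invalid_argument")
})

test_that("binomial test: closed forms and enumeration", {
  expect_equal(binomial_test(8, 10), (45 + 10 + 1) / 1024)
  expect_equal(binomial_test(10, 10), 0.5^10)
  expect_gt(binomial_test(5, 10), 0.5)
  # enumeration oracle for a non-uniform p0
  k <- 7; n <- 9; p0 <- 0.3
  expect_equal(binomial_test(k, n, p0),
               sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n))),
               tolerance = 1e-12)
  # two-sided small-mass method on a symmetric null
  expect_equal(binomial_test(8, 10, alternative = "two.sided"),
               2 * binomial_test(8, 10), tolerance = 1e-9)
  expect_error(binomial_test(11, 10), class = "echosynth_invalid_argument")

  # survey-scale sanity: accuracies reported for pooled expert groups
  expect_lt(binomial_test(round(0.637 * 135), 135), 0.05)
  expect_gt(binomial_test(round(0.533 * 315), 315), 0.05)
})
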