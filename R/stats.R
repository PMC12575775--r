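# Agreement and hypothesis-testing statistics used in the evaluation.

#' Bland-Altman agreement analysis
#'
#' Differences d = estimate - reference; bias = mean(d); limits of
#' agreement = bias -/+ 1.96 * sd(d) with the sample (n - 1) standard
#' deviation.
#'
#' @param reference,estimates equal-length numeric vectors, n >= 2.
#' @return object of class `agreement_result`: list with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(reference, estimates) {
  if (length(reference) != length(estimates))
    abort_invalid("`reference` and `estimates` lengths differ")
  if (length(reference) < 2) abort_invalid("need n >= 2")
  d <- estimates - reference
  s <- stats::sd(d)
  structure(list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, sd_diff = s,
                 n = length(d)), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement> bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-sided paired signed-rank test: zero differences are dropped; for
#' n <= 25 without ties in |d| the exact null distribution is used,
#' otherwise a tie-corrected normal approximation. The raw p-value is
#' Bonferroni-adjusted for `m` comparisons.
#'
#' @param scores_a,scores_b equal-length paired score vectors.
#' @param m number of comparisons for the Bonferroni correction.
#' @param alpha significance level applied to the adjusted p.
#' @return list with `statistic` (V, rank sum of positive differences),
#'   `p_value`, `p_adjusted`, `significant`, `n` (non-zero pairs),
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_bonferroni <- function(scores_a, scores_b, m = 6L, alpha = 0.05) {
  if (length(scores_a) != length(scores_b))
    abort_invalid("paired score lengths differ")
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    abort_invalid("all differences zero: test undefined",
                  class = "echosynth_undefined_test")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(V, n),
                 1 - stats::psignrank(V - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  p_adj <- min(1, m * p)
  list(statistic = V, p_value = p, p_adjusted = p_adj,
       significant = p_adj < alpha, n = n, method = method)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with p_e
#' from the marginal products. If both raters are constant and identical
#' (p_e = 1) kappa is defined as 1; constant but different raters yield 0.
#'
#' @param ratings_1,ratings_2 equal-length categorical vectors.
#' @return scalar <= 1.
#' @export
cohens_kappa <- function(ratings_1, ratings_2) {
  if (length(ratings_1) != length(ratings_2))
    abort_invalid("rating lengths differ")
  lev <- union(unique(ratings_1), unique(ratings_2))
  f1 <- factor(ratings_1, levels = lev)
  f2 <- factor(ratings_2, levels = lev)
  tab <- table(f1, f2) / length(f1)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Average pairwise Cohen's kappa
#'
#' Within one group (all distinct rater pairs) or between two groups (all
#' cross pairs).
#'
#' @param group_1 list of rating vectors (one per rater).
#' @param group_2 optional second group; if given, cross-pair average.
#' @return mean kappa.
#' @export
average_pairwise_kappa <- function(group_1, group_2 = NULL) {
  if (is.null(group_2)) {
    n <- length(group_1)
    if (n < 2) abort_invalid("need >= 2 raters for within-group kappa")
    pairs <- utils::combn(n, 2)
    mean(apply(pairs, 2, function(ij)
      cohens_kappa(group_1[[ij[1]]], group_1[[ij[2]]])))
  } else {
    mean(outer(seq_along(group_1), seq_along(group_2),
               Vectorize(function(i, j)
                 cohens_kappa(group_1[[i]], group_2[[j]]))))
  }
}

#' Exact binomial test
#'
#' One-sided (greater) tail probability of k or more successes in n
#' trials under success probability `p0`, from the exact binomial mass;
#' `alternative = "two.sided"` sums all outcome masses not exceeding the
#' observed one (small-mass method).
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @param alternative "greater" (default) or "two.sided".
#' @return p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.5, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (k < 0 || k > n) abort_invalid("`k` must be in [0, n]")
  mass <- stats::dbinom(0:n, n, p0)
  if (alternative == "greater") {
    sum(mass[(k + 1):(n + 1)])
  } else {
    min(1, sum(mass[mass <= mass[k + 1] * (1 + 1e-7)]))
  }
}
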