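# Paired model comparison (exact Wilcoxon signed-rank with Bonferroni
# correction) and the point-biserial correlation used to relate
# classification to reconstruction performance.

signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]                      # classical treatment: drop zeros
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p = 1, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 15) {
    # exact null by enumerating all 2^n sign assignments; valid under ties
    w_all <- vapply(0:(2^n - 1L), function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L])
    }, 0)
    p <- switch(alternative,
      greater = mean(w_all >= W),
      less = mean(w_all <= W),
      two.sided = min(1, 2 * min(mean(w_all >= W), mean(w_all <= W))))
  } else if (!ties && n <= 25) {
    p <- switch(alternative,
      greater = stats::psignrank(W - 1, n, lower.tail = FALSE),
      less = stats::psignrank(W, n),
      two.sided = min(1, 2 * min(stats::psignrank(W - 1, n, lower.tail = FALSE),
                                 stats::psignrank(W, n))))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sig2)
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, p = max(p, .Machine$double.xmin), n = n)
}

#' Paired Wilcoxon signed-rank comparison with Bonferroni correction
#'
#' Tests whether per-subject accuracies of model A exceed those of model B
#' (one-sided by default). The null distribution is exact for n <= 15
#' (full enumeration of sign assignments, valid under tied ranks), exact
#' via the signed-rank distribution for n <= 25 without ties, and a
#' tie-corrected normal approximation beyond. Zero differences are
#' dropped. The per-test alpha is the family alpha divided by the number
#' of comparisons.
#'
#' @param acc_a,acc_b equal-length per-subject accuracy vectors.
#' @param alternative "greater" (A > B), "less" or "two.sided".
#' @param n_comparisons number of tests in the family (Bonferroni divisor).
#' @param family_alpha family-wise Type 1 error level.
#' @return a `comparison_report`: `statistic` (W+), `p_value`,
#'   `alpha_corrected`, `reject`, `n_effective`.
#' @export
wilcoxon_compare <- function(acc_a, acc_b, alternative = "greater",
                             n_comparisons = 1L, family_alpha = 0.05) {
  abort_if(length(acc_a) != length(acc_b), "accuracy vectors must have equal length")
  abort_if(length(acc_a) < 5, "need n >= 5 paired observations")
  res <- signed_rank_p(acc_a - acc_b, alternative)
  alpha <- family_alpha / n_comparisons
  structure(list(statistic = res$statistic, p_value = res$p,
                 alpha_corrected = alpha,
                 reject = if (res$n == 0) NA else res$p < alpha,
                 n_effective = res$n, alternative = alternative),
            class = "comparison_report")
}

#' Point-biserial correlation
#'
#' Correlation between a binary indicator (e.g. per-image classifier
#' correctness) and a continuous score (e.g. per-image reconstruction
#' accuracy); algebraically identical to the Pearson correlation with the
#' indicator coded 0/1.
#'
#' @param binary 0/1 vector, both groups non-empty.
#' @param scores real vector of the same length.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
point_biserial <- function(binary, scores) {
  abort_if(length(binary) != length(scores), "inputs must have equal length")
  abort_if(!all(binary %in% c(0, 1)), "binary must be coded 0/1")
  n1 <- sum(binary == 1); n0 <- sum(binary == 0); n <- length(binary)
  abort_if(n1 == 0 || n0 == 0, "both groups must be non-empty")
  s <- sqrt(sum((scores - mean(scores))^2) / n)   # population SD
  abort_if(s == 0, "scores are constant; correlation undefined")
  (mean(scores[binary == 1]) - mean(scores[binary == 0])) / s * sqrt(n1 * n0 / n^2)
}
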