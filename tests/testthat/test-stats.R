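# exhaustive signed-rank null: distribution of W+ over all sign patterns
enumerate_signed_rank <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  switch(alternative,
         greater = mean(w_all >= w_obs),
         less = mean(w_all <= w_obs),
         two.sided = min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs))))
}

test_that("signed-rank p-values match exhaustive enumeration for n <= 10", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(5:10, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    for (alt in c("greater", "less", "two.sided")) {
      got <- wilcoxon_compare(a, b, alternative = alt)$p_value
      expect_equal(got, enumerate_signed_rank(a - b, alt), tolerance = 1e-12,
                   info = paste("n =", n, "alt =", alt))
    }
  }
})

test_that("uniformly positive differences at n = 8 give p = 1/256", {
  a <- c(52.5, 40.2, 15.5, 51.2, 11.5, 29.3, 48.7, 25.9)   # A beats B everywhere
  b <- a - stats::runif(8, 1, 5)
  res <- wilcoxon_compare(a, b, alternative = "greater")
  expect_equal(res$p_value, 1 / 256)
  expect_equal(enumerate_signed_rank(a - b, "greater"), 1 / 256)
})

test_that("Bonferroni correction divides the family alpha", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8); b <- a - 1
  res <- wilcoxon_compare(a, b, n_comparisons = 5L, family_alpha = 0.05)
  expect_equal(res$alpha_corrected, 0.01)
  expect_true(res$reject)                         # p = 1/256 < 0.01
  # identical vectors: all differences zero, p = 1, no decision
  res0 <- wilcoxon_compare(a, a)
  expect_equal(res0$p_value, 1)
  expect_true(is.na(res0$reject))
})

test_that("point-biserial equals the Pearson formula to 1e-12", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    bin <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(bin)) < 2) next
    sc <- stats::rnorm(n) + bin * stats::runif(1, -1, 1)
    expect_equal(point_biserial(bin, sc), stats::cor(bin, sc), tolerance = 1e-12)
  }
})

test_that("point-biserial hits the separation and independence anchors", {
  expect_equal(point_biserial(c(0, 0, 0, 1, 1, 1), c(2, 2, 2, 7, 7, 7)), 1)
  set.seed(2)
  bin <- rep(c(0, 1), 4000)
  expect_lt(abs(point_biserial(bin, stats::rnorm(8000))), 0.04)
  expect_error(point_biserial(c(0, 1), c(3, 3)), "constant")
  expect_error(point_biserial(c(1, 1), c(1, 2)), "non-empty")
})
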