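test_that("the noise schedule has strictly decreasing alpha_bar in (0,1]", {
  sch <- diffusion_schedule(1000L)
  expect_length(sch$alpha_bar, 1000L)
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_true(all(sch$alpha_bar > 0 & sch$alpha_bar <= 1))
  expect_lt(sch$alpha_bar[1000], 0.01)            # end state is near-pure noise
})

test_that("cross-attention matches an explicit-loop oracle", {
  set.seed(11)
  phi <- matrix(stats::rnorm(5 * 6), 5, 6)
  ctx <- matrix(stats::rnorm(3 * 4), 3, 4)
  wq <- matrix(stats::rnorm(36), 6, 6)
  wk <- matrix(stats::rnorm(24), 4, 6)
  wv <- matrix(stats::rnorm(24), 4, 6)
  got <- cross_attention(phi, ctx, wq, wk, wv)
  q <- phi %*% wq; k <- ctx %*% wk; v <- ctx %*% wv
  oracle <- matrix(0, 5, 6)
  for (i in 1:5) {
    s <- vapply(1:3, function(m) sum(q[i, ] * k[m, ]) / sqrt(6), 0)
    a <- exp(s - max(s)); a <- a / sum(a)
    oracle[i, ] <- colSums(a * v)
  }
  expect_lt(max(abs(got$out - oracle)), 1e-10)
  expect_true(all(abs(rowSums(got$weights) - 1) < 1e-6))
  # a single context token collapses every query onto that token's value
  got1 <- cross_attention(phi, ctx[1, , drop = FALSE], wq, wk, wv)
  expect_equal(got1$out, matrix(rep((ctx[1, , drop = FALSE] %*% wv), each = 5), 5),
               tolerance = 1e-12)
  expect_error(cross_attention(phi, ctx, wk, wq, wv), "mismatch")
})

test_that("the diffusion objective hits its analytic anchors", {
  cfg <- denoiser_config(latent_hw = 4L, latent_c = 2L, width = 4L,
                         d_t = 8L, d_tau = 6L, d_k = 6L, m_tokens = 4L,
                         embed_dim = 16L)
  sch <- diffusion_schedule(100L)
  z <- array(stats::rnorm(8 * 4 * 4 * 2), dim = c(8, 4, 4, 2))
  y <- matrix(stats::rnorm(8 * 16), 8, 16)
  # an oracle model that returns the injected noise exactly -> loss 0
  injected <- NULL
  capture <- function(zt, t, yv) {
    ab <- sch$alpha_bar[t]
    eps <- zt
    for (i in seq_along(t)) eps[i, , , ] <- (zt[i, , , ] - sqrt(ab[i]) * z[i, , , ]) / sqrt(1 - ab[i])
    eps
  }
  set.seed(1)
  expect_lt(diffusion_loss(z, y, NULL, cfg, sch, model = capture)$loss, 1e-20)
  # an all-zero model has expected loss E[eps^2] = 1 (Monte-Carlo, 3 SE)
  zero_model <- function(zt, t, yv) array(0, dim = dim(zt))
  set.seed(2)
  big_z <- array(stats::rnorm(40 * 4 * 4 * 2), dim = c(40, 4, 4, 2))
  big_y <- matrix(0, 40, 16)
  losses <- vapply(1:10, function(i) {
    diffusion_loss(big_z * 0, big_y, NULL, cfg, sch, model = zero_model)$loss
  }, 0)
  n_draws <- 10 * length(big_z)
  expect_lt(abs(mean(losses) - 1), 3 * sqrt(2 / n_draws))
  # real model: loss is finite and nonnegative, both conditioning modes
  p <- with_seed(3, denoiser_params(cfg))
  set.seed(4)
  for (dc in c(TRUE, FALSE)) {
    l <- diffusion_loss(z, y, p, cfg, sch, double_cond = dc)$loss
    expect_true(is.finite(l) && l >= 0)
  }
})

test_that("PLMS is deterministic and solves the constant-noise model in closed form", {
  cfg <- denoiser_config(latent_hw = 4L, latent_c = 2L, width = 4L,
                         d_t = 8L, d_tau = 6L, d_k = 6L, m_tokens = 4L,
                         embed_dim = 16L)
  sch <- diffusion_schedule(60L)
  y <- stats::rnorm(16)
  cst <- array(0.4, dim = c(1, 4, 4, 2))
  model <- function(zt, t, yv) cst
  s1 <- sample_plms(NULL, cfg, sch, y, steps = 12L, seed = 7, model = model)
  s2 <- sample_plms(NULL, cfg, sch, y, steps = 12L, seed = 7, model = model)
  expect_identical(s1, s2)
  # with eps independent of z_t and t, any number of steps equals the
  # single-step solution x0 = (x_T - sqrt(1 - ab_T) eps) / sqrt(ab_T)
  x0 <- with_seed(7, array(stats::rnorm(4 * 4 * 2), dim = c(1, 4, 4, 2)))
  abT <- sch$alpha_bar[60]
  closed <- (x0[1, , , ] - sqrt(1 - abT) * 0.4) / sqrt(abT)
  expect_lt(max(abs(s1 - closed)), 1e-10)
  for (steps in c(1L, 5L, 30L)) {
    expect_lt(max(abs(sample_plms(NULL, cfg, sch, y, steps = steps, seed = 7,
                                  model = model) - closed)), 1e-10)
  }
  expect_error(sample_plms(NULL, cfg, sch, y, steps = 61L, model = model), "steps")
})

test_that("the latent codec compresses 12x and beats the mean-image baseline", {
  sys <- toy_system()
  ae <- sys$ae
  n_img_el <- 32 * 32 * 3
  n_lat_el <- ae$latent_hw^2 * ae$latent_c
  expect_equal(n_img_el / n_lat_el, 12)
  x <- sys$arr$x[1:8, , , , drop = FALSE]
  z <- ae_encode(ae, x)
  expect_equal(dim(z), c(8L, 8L, 8L, 4L))
  expect_equal(dim(ae_decode(ae, z)), dim(x))
  expect_lt(ae$holdout_mse, ae$baseline_mse)
})

test_that("the surrogate metric classifier separates the stimulus classes", {
  sys <- toy_system()
  sc <- surrogate_scores(sys$clf, sys$arr$x)
  acc <- mean(max.col(sc) == sys$arr$labels + 1L)
  expect_gt(acc, 0.9)
})
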