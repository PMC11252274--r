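test_that("the n-way metric hits its analytic anchors", {
  k <- 20L
  # a classifier that always ranks the truth first
  perfect <- diag(k) * 0.9 + 0.005
  r <- n_way_top1(NULL, 0:(k - 1L), NULL, n = k, trials = 50L, seed = 1,
                  scores = perfect)
  expect_equal(r$accuracy, 1)
  # n = 1 is trivially correct
  r1 <- n_way_top1(NULL, 0:(k - 1L), NULL, n = 1L, trials = 10L, seed = 1,
                   scores = perfect)
  expect_equal(r1$accuracy, 1)
  # i.i.d. random scores sit at chance 1/n (Monte-Carlo, 3 SE)
  set.seed(4)
  n_img <- 60L
  rand <- matrix(stats::runif(n_img * 50L), n_img, 50L)
  for (n in c(10L, 50L)) {
    r <- n_way_top1(NULL, sample(0:49, n_img, TRUE), NULL, n = n,
                    trials = 400L, seed = 2, scores = rand)
    se <- sqrt((1 / n) * (1 - 1 / n) / n_img)     # per-image binomial-ish bound
    expect_lt(abs(r$accuracy - 1 / n), 3 * se)
  }
  expect_error(n_way_top1(NULL, 0:19, NULL, n = 60L, scores = perfect), "exceeds")
})

test_that("fine-tuning updates exactly the conditioning pathway", {
  sys <- toy_system()
  before <- sys$pretrained$denoiser
  after <- sys$ft$ldm$denoiser
  trainable <- sys$ft$trainable
  expect_setequal(trainable, c("attn_wq", "attn_wk", "attn_wv", "attn_wo",
                               "tau_w", "tau_b", "sig_w", "sig_b"))
  for (nm in setdiff(names(before), trainable)) {
    expect_identical(before[[nm]], after[[nm]])   # frozen weights, bitwise
  }
  for (nm in trainable) {
    expect_false(identical(before[[nm]], after[[nm]]))
  }
  # the fine-tuning loss trends down
  h <- sys$ft$history
  expect_lt(mean(utils::tail(h, 30)), mean(utils::head(h, 30)))
})

test_that("sampling is seed-deterministic through the full toy system", {
  sys <- toy_system()
  emb <- extract_embedding(sys$ft$encoder, sys$epochs[[5]]$data[1:2, , , drop = FALSE])
  z1 <- sample_plms(sys$ft$ldm$denoiser, sys$dcfg, sys$sch, emb[1, ],
                    steps = 10L, seed = 3)
  z2 <- sample_plms(sys$ft$ldm$denoiser, sys$dcfg, sys$sch, emb[1, ],
                    steps = 10L, seed = 3)
  expect_identical(z1, z2)
  img <- ae_decode(sys$ae, array(z1 / sys$lat$scale, dim = c(1, dim(z1))))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("more sampling steps change the output smoothly", {
  sys <- toy_system()
  emb <- extract_embedding(sys$ft$encoder, sys$epochs[[5]]$data[1:1, , , drop = FALSE])
  zs <- lapply(c(5L, 10L, 20L, 40L), function(s) {
    sample_plms(sys$ft$ldm$denoiser, sys$dcfg, sys$sch, emb[1, ],
                steps = s, seed = 5)
  })
  d <- vapply(1:3, function(i) mean(abs(zs[[i + 1]] - zs[[i]])), 0)
  expect_lt(d[3], d[1])                           # refinement shrinks updates
})

test_that("the null control builds normalized 500-sample windows", {
  sys <- toy_system()
  rec <- sys$sessions[[5]]
  spec <- sys$spec
  isi <- spec$step_samps - spec$stim_samps
  win <- rec$events$onset_sample[1] + spec$stim_samps + seq_len(isi)
  seg <- rec$signal[, win]
  up <- stats::approx(seq_len(isi), seg[1, ], n = spec$stim_samps)$y
  expect_length(up, 500L)
  # the normalized null epochs have per-channel zero mean
  nullr <- null_control(rec, sys$ft$encoder, sys$ft$ldm, sys$clf,
                        n_trials = 4L, n_samples = 1L, plms_steps = 5L,
                        n_way = 20L, mc_trials = 20L, seed = 11)
  expect_s3_class(nullr, "reconstruction_report")
  expect_true(all(nullr$best_per_image >= 0 & nullr$best_per_image <= 1))
})

test_that("best-of-5 never falls below mean-of-5", {
  sys <- toy_system()
  test_ep <- sys$epochs[[5]]
  sel <- which(test_ep$labels %in% 0:3)[1:4]
  rep <- reconstruct_images(sys$ft$encoder, sys$ft$ldm,
                            test_ep$data[sel, , , drop = FALSE],
                            test_ep$labels[sel], sys$clf,
                            n_samples = 3L, plms_steps = 8L, n_way = 20L,
                            mc_trials = 50L, seed = 13)
  expect_gte(rep$best_of, rep$mean_of)
  expect_true(all(rep$best_per_image >= rep$mean_per_image - 1e-12))
})
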