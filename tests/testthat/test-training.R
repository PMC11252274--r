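test_that("the one-cycle schedule warms up to max_lr and anneals far below it", {
  total <- 200L; max_lr <- 1e-2
  lrs <- vapply(seq_len(total), one_cycle_lr, 0, total_steps = total, max_lr = max_lr)
  warm <- round(0.3 * total)
  expect_equal(which.max(lrs), warm)
  expect_equal(max(lrs), max_lr)
  expect_equal(lrs[1], max_lr / 25, tolerance = 1e-12)
  expect_equal(lrs[total], max_lr / 1e4, tolerance = 1e-4)
  expect_lt(lrs[total], lrs[1])
  # closed form at interior points
  expect_equal(one_cycle_lr(30, total, max_lr),
               max_lr / 25 + (max_lr - max_lr / 25) * (1 - cos(pi * 29 / 59)) / 2)
  expect_true(all(diff(lrs[1:warm]) >= 0))
  expect_true(all(diff(lrs[(warm + 1):total]) <= 0))
})

test_that("training reduces loss on separable data and is seed-deterministic", {
  spec <- session_spec(5L, 10L)
  m <- vep_model(spec, snr = 2)
  rec <- synthesize_recording(make_session_events(spec, 1), m, seed = 1)
  ep <- preprocess_session(rec)
  cfg <- eegnet_config(f1 = 4L, temporal_kernel = 16L, n_classes = 5L)
  tc <- train_config(epochs = 4L, max_lr = 5e-3, batch_size = 16L, seed = 3L)
  r1 <- train_classifier(build_eegnet(cfg, 1), ep, NULL, tc)
  expect_lt(utils::tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  expect_equal(nrow(r1$history), 4L)
  expect_true(all(c("lr", "train_loss", "train_acc") %in% names(r1$history)))
  r2 <- train_classifier(build_eegnet(cfg, 1), ep, NULL, tc)
  expect_identical(r1$handle$params, r2$handle$params)
})

test_that("the hold-out split picks the cleanest recording as test", {
  mk <- function(drops, id) {
    e <- new_epoch_set(array(0, c(2, 2, 2)), c(0L, 1L), rep(TRUE, 2), id, 250L)
    e$n_total <- 10L + drops
    e$retained <- c(rep(TRUE, 10L), rep(FALSE, drops))
    e
  }
  recs <- list(mk(5L, "a"), mk(0L, "b"), mk(2L, "c"))
  sp <- make_split(recs)
  expect_equal(sp$test, 2L)
  expect_equal(sp$val, 3L)
  expect_equal(sp$train, 1L)
  expect_length(intersect(sp$test, c(sp$train, sp$val)), 0L)
  # tie on drops: lowest session index wins
  sp2 <- make_split(list(mk(1L, "a"), mk(1L, "b"), mk(1L, "c"), mk(1L, "d")))
  expect_equal(sp2$test, 1L)
  expect_equal(sp2$val, 2L)
  expect_error(make_split(recs[1:2]), "3")
})

test_that("evaluation reports satisfy the confusion-matrix invariants", {
  spec <- tiny_spec()
  m <- vep_model(spec, snr = 2)
  ep <- preprocess_session(synthesize_recording(make_session_events(spec, 2), m, seed = 4))
  cfg <- eegnet_config(f1 = 2L, temporal_kernel = 8L, n_classes = 4L)
  h <- build_eegnet(cfg, seed = 5)
  rep <- evaluate(h, ep)
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(factor(ep$labels, 0:3))))
  expect_equal(rep$accuracy, 100 * sum(diag(rep$confusion)) / rep$n)
  expect_equal(length(rep$per_class), 4L)
})

test_that("a uniform-random predictor scores 5% on balanced 20-class data", {
  k <- 20L; n_per <- 1000L
  truth <- rep(0:(k - 1L), each = n_per)
  pred <- with_seed(1, sample(0:(k - 1L), length(truth), replace = TRUE))
  acc <- 100 * mean(pred == truth)
  expect_equal(acc, 5, tolerance = 0.15)          # 3 SE of the binomial
  # exact expectation
  expect_equal(100 / k, 5)
})

test_that("grid search returns one row per config and retrains on train+val", {
  spec <- tiny_spec()
  m <- vep_model(spec, snr = 2)
  recs <- lapply(1:3, function(s) {
    preprocess_session(synthesize_recording(make_session_events(spec, s), m,
                                            seed = 10 + s,
                                            session_id = sprintf("S%d", s)))
  })
  split <- make_split(recs)
  grid <- list(eegnet_config(f1 = 2L, temporal_kernel = 8L, n_classes = 4L),
               eegnet_config(f1 = 4L, temporal_kernel = 8L, n_classes = 4L))
  tc <- train_config(epochs = 2L, max_lr = 3e-3, batch_size = 10L, seed = 1L)
  gs <- grid_search(grid, recs, split, tc)
  expect_equal(nrow(gs$table), 2L)
  expect_s3_class(gs$best_config, "eegnet_config")
  expect_s3_class(gs$handle, "model_handle")
  # single-config grid returns that config
  gs1 <- grid_search(grid[1], recs, split, tc)
  expect_identical(gs1$best_config, grid[[1]])
})

test_that("cross-validation holds out every non-test recording exactly once", {
  spec <- tiny_spec()
  m <- vep_model(spec, snr = 2)
  recs <- lapply(1:4, function(s) {
    preprocess_session(synthesize_recording(make_session_events(spec, s), m,
                                            seed = 30 + s,
                                            session_id = sprintf("S%d", s)))
  })
  cfg <- eegnet_config(f1 = 2L, temporal_kernel = 8L, n_classes = 4L)
  cv <- cross_validate(cfg, recs, train_config(epochs = 2L, batch_size = 10L, seed = 1L))
  expect_length(cv$fold_acc, 3L)                  # 4 recordings, 1 test
  expect_true(all(cv$fold_acc >= 0 & cv$fold_acc <= 100))
  expect_equal(cv$mean_acc, mean(cv$fold_acc))
})
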