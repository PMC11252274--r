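test_that("the best configuration has 62,612 parameters, matching the layer accounting", {
  h <- build_eegnet(eegnet_config())
  inv <- parameter_inventory(h)
  # independent closed-form accounting per layer
  expected <- c(conv1_w = 64 * 64, bn1_g = 64, bn1_b = 64,
                dw_w = 64 * 2 * 8, bn2_g = 128, bn2_b = 128,
                sep_dw_w = 128 * 16, sep_pw_w = 128 * 128,
                bn3_g = 128, bn3_b = 128,
                fc_w = 128 * 15 * 20, fc_b = 20)
  expect_equal(stats::setNames(inv$count, inv$layer), expected)
  expect_equal(n_parameters(h), 62612L)
  expect_equal(sum(expected), 62612L)
})

test_that("logit shapes, softmax normalization and embedding geometry hold", {
  cfg <- eegnet_config(f1 = 4L, temporal_kernel = 16L)
  h <- build_eegnet(cfg, seed = 1)
  x <- array(stats::rnorm(5 * 8 * 500), dim = c(5, 8, 500))
  lg <- predict_logits(h, x)
  expect_equal(dim(lg), c(5L, 20L))
  expect_true(all(abs(rowSums(softmax_rows(lg)) - 1) < 1e-6))
  hp <- build_eegnet_plus(cfg, 512L, seed = 1)
  emb <- extract_embedding(hp, x)
  expect_equal(dim(emb), c(5L, 512L))
  expect_true(all(is.finite(emb)))
  expect_equal(dim(predict_logits(hp, x)), c(5L, 20L))
  # same epoch twice: identical embeddings (eval-mode determinism)
  expect_identical(emb, extract_embedding(hp, x))
  expect_error(extract_embedding(h, x), "encoder")
})

test_that("EEGNet and EEGNet+ share identical backbone parameter counts", {
  cfg <- eegnet_config()
  a <- parameter_inventory(build_eegnet(cfg))
  b <- parameter_inventory(build_eegnet_plus(cfg))
  backbone <- setdiff(a$layer, c("fc_w", "fc_b"))
  expect_equal(a$count[match(backbone, a$layer)], b$count[match(backbone, b$layer)])
})

test_that("analytic gradients match finite differences for both heads", {
  cfg <- grad_config()
  x <- with_seed(42, array(stats::rnorm(3 * 4 * 12), dim = c(3, 4, 12)))
  y <- c(1L, 2L, 3L)
  for (h in list(build_eegnet(cfg, seed = 9), build_eegnet_plus(cfg, 7L, seed = 9))) {
    lossfun <- function(hh) softmax_xent(eegnet_forward(hh, x, TRUE)$logits, y)$loss
    fw <- eegnet_forward(h, x, TRUE)
    g <- eegnet_backward(h, fw$cache, softmax_xent(fw$logits, y)$dlogits)
    eps <- 1e-5
    set.seed(7)
    for (nm in names(g)) {
      for (j in sample(seq_along(g[[nm]]), min(3L, length(g[[nm]])))) {
        hp <- h; hp$params[[nm]][j] <- hp$params[[nm]][j] + eps
        hm <- h; hm$params[[nm]][j] <- hm$params[[nm]][j] - eps
        gn <- (lossfun(hp) - lossfun(hm)) / (2 * eps)
        expect_lt(abs(gn - g[[nm]][j]) / max(1e-6, abs(gn) + abs(g[[nm]][j])), 1e-3)
      }
    }
  }
})

test_that("logits are permutation-equivariant under output relabeling", {
  cfg <- eegnet_config(f1 = 4L, temporal_kernel = 16L, n_classes = 6L)
  h <- build_eegnet(cfg, seed = 3)
  x <- array(stats::rnorm(4 * 8 * 500), dim = c(4, 8, 500))
  base <- predict_logits(h, x)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  h2 <- h
  h2$params$fc_w <- h$params$fc_w[, perm]
  h2$params$fc_b <- h$params$fc_b[perm]
  expect_equal(predict_logits(h2, x), base[, perm], tolerance = 1e-12)
})

test_that("dropout is active only in training mode", {
  cfg <- eegnet_config(f1 = 4L, temporal_kernel = 16L, dropout_p = 0.5)
  h <- build_eegnet(cfg, seed = 2)
  x <- array(stats::rnorm(2 * 8 * 500), dim = c(2, 8, 500))
  e1 <- eegnet_forward(h, x, training = FALSE)$logits
  e2 <- eegnet_forward(h, x, training = FALSE)$logits
  expect_identical(e1, e2)
  set.seed(1); t1 <- eegnet_forward(h, x, training = TRUE)$logits
  set.seed(2); t2 <- eegnet_forward(h, x, training = TRUE)$logits
  expect_false(identical(t1, t2))
})
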