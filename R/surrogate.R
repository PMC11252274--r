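# Surrogate metric classifier: a small CNN trained on the synthetic
# stimulus classes, used to score generated images in the n-way top-1
# evaluation.

surrogate_params <- function(n_classes, w1 = 12L, w2 = 24L) {
  list(c1_w = he_init(c(3, 3, 3, w1), 27), c1_b = rep(0, w1),
       c2_w = he_init(c(3, 3, w1, w2), 9 * w1), c2_b = rep(0, w2),
       fc_w = he_init(c(w2, n_classes), w2), fc_b = rep(0, n_classes))
}

surrogate_fwd <- function(p, x) {
  c1 <- conv2d_fwd(x, p$c1_w, p$c1_b, stride = 2L, pad = 1L)
  a1 <- elu_fwd(c1$out)
  c2 <- conv2d_fwd(a1$out, p$c2_w, p$c2_b, stride = 2L, pad = 1L)
  a2 <- elu_fwd(c2$out)
  gp <- gap_fwd(a2$out)
  fc <- dense_fwd(gp$out, p$fc_w, p$fc_b)
  list(logits = fc$out,
       cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                    a2 = a2$cache, gp = gp$cache, fc = fc$cache))
}

surrogate_bwd <- function(p, dlogits, cache) {
  g <- list()
  d <- dense_bwd(dlogits, p$fc_w, cache$fc); g$fc_w <- d$dW; g$fc_b <- d$db
  dx <- gap_bwd(d$dx, cache$gp)
  dx <- elu_bwd(dx, cache$a2)
  b2 <- conv2d_bwd(dx, p$c2_w, cache$c2); g$c2_w <- b2$dW; g$c2_b <- b2$db
  dx <- elu_bwd(b2$dx, cache$a1)
  b1 <- conv2d_bwd(dx, p$c1_w, cache$c1); g$c1_w <- b1$dW; g$c1_b <- b1$db
  g
}

# mild corruption so the metric stays reliable on imperfect generations:
# pixel noise, brightness scaling, and an occasional box blur
augment_batch <- function(x) {
  d <- dim(x)
  x <- x * stats::runif(d[1], 0.8, 1.15)[slice.index(x, 1)] +
    array(stats::rnorm(length(x), 0, 0.04), dim = d)
  if (stats::runif(1) < 0.5) {
    h <- d[2]; w <- d[3]
    x <- (x[, c(1, 1:(h - 1)), , , drop = FALSE] +
            x[, c(2:h, h), , , drop = FALSE] +
            x[, , c(1, 1:(w - 1)), , drop = FALSE] +
            x[, , c(2:w, w), , drop = FALSE] + 2 * x) / 6
  }
  pmin(pmax(x, 0), 1)
}

#' Train the surrogate image classifier
#'
#' Trained with light corruption (noise, brightness jitter, blur) so that
#' its scores remain informative on imperfect generated images, standing
#' in for the robust pretrained classifier a full-scale metric would use.
#'
#' @param images `(n, side, side, 3)` array or a `stimulus_set`.
#' @param labels 0-based class labels (taken from the set if omitted).
#' @param n_classes number of classes.
#' @param epochs,batch_size,lr training settings.
#' @param augment corrupt training batches (on by default).
#' @param seed run seed.
#' @return a `surrogate_classifier` with params, class count and final
#'   training accuracy.
#' @export
train_surrogate <- function(images, labels = NULL, n_classes = NULL,
                            epochs = 40L, batch_size = 32L, lr = 5e-3,
                            augment = TRUE, seed = 1L) {
  if (inherits(images, "stimulus_set")) {
    arr <- stimulus_array(images)
    images <- arr$x
    labels <- arr$labels
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n <- dim(images)[1]
  p <- with_seed(seed, surrogate_params(n_classes))
  state <- adamw_init(p)
  acc <- 0
  with_seed(seed + 1L, {
    steps <- max(1L, n %/% batch_size)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      acc <- 0
      for (bs in seq_len(steps)) {
        idx <- ord[((bs - 1L) * batch_size + 1L):min(n, bs * batch_size)]
        xb <- images[idx, , , , drop = FALSE]
        if (augment) xb <- augment_batch(xb)
        fw <- surrogate_fwd(p, xb)
        sx <- softmax_xent(fw$logits, labels[idx] + 1L)
        g <- surrogate_bwd(p, sx$dlogits, fw$cache)
        upd <- adamw_step(p, g, state, lr, weight_decay = 1e-5,
                          decay_mask = decay_params(p))
        p <- upd$params; state <- upd$state
        acc <- acc + mean(max.col(sx$probs) == labels[idx] + 1L)
      }
      acc <- acc / steps
    }
  })
  structure(list(params = p, n_classes = as.integer(n_classes),
                 train_acc = acc), class = "surrogate_classifier")
}

#' Class probabilities from the surrogate classifier
#' @param clf a `surrogate_classifier`.
#' @param images `(n, side, side, 3)` array.
#' @return `(n, n_classes)` matrix of softmax probabilities.
#' @export
surrogate_scores <- function(clf, images) {
  softmax_rows(surrogate_fwd(clf$params, images)$logits)
}
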