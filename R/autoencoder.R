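# Small convolutional latent autoencoder: the image codec whose latent
# space the diffusion model operates in. A plain (non-quantized)
# autoencoder is the default codec.

#' Stack a stimulus set into an image array
#' @param set a `stimulus_set`.
#' @return list with `x` (n, side, side, 3) array, `labels` (0-based class
#'   ids), `image_ids`.
#' @export
stimulus_array <- function(set) {
  n <- length(set$images) * length(set$images[[1]])
  side <- set$side_px
  x <- array(0, dim = c(n, side, side, 3))
  labels <- integer(n); image_ids <- integer(n)
  i <- 0L
  for (ci in seq_along(set$images)) {
    for (ii in seq_along(set$images[[ci]])) {
      i <- i + 1L
      x[i, , , ] <- set$images[[ci]][[ii]]
      labels[i] <- ci - 1L
      image_ids[i] <- ii - 1L
    }
  }
  list(x = x, labels = labels, image_ids = image_ids)
}

autoencoder_params <- function(side, latent_c, width) {
  list(
    e1_w = he_init(c(3, 3, 3, width), 27), e1_b = rep(0, width),
    e2_w = he_init(c(3, 3, width, latent_c), 9 * width), e2_b = rep(0, latent_c),
    d1_w = he_init(c(3, 3, latent_c, width), 9 * latent_c), d1_b = rep(0, width),
    d2_w = he_init(c(3, 3, width, width), 9 * width), d2_b = rep(0, width),
    d3_w = he_init(c(3, 3, width, 3), 9 * width), d3_b = rep(0, 3)
  )
}

ae_encode_fwd <- function(p, x) {
  c1 <- conv2d_fwd(x, p$e1_w, p$e1_b, stride = 2L, pad = 1L)
  a1 <- elu_fwd(c1$out)
  c2 <- conv2d_fwd(a1$out, p$e2_w, p$e2_b, stride = 2L, pad = 1L)
  list(out = c2$out, cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache))
}

ae_decode_fwd <- function(p, z) {
  c1 <- conv2d_fwd(z, p$d1_w, p$d1_b, stride = 1L, pad = 1L)
  a1 <- elu_fwd(c1$out)
  u1 <- upsample2_fwd(a1$out)
  c2 <- conv2d_fwd(u1$out, p$d2_w, p$d2_b, stride = 1L, pad = 1L)
  a2 <- elu_fwd(c2$out)
  u2 <- upsample2_fwd(a2$out)
  c3 <- conv2d_fwd(u2$out, p$d3_w, p$d3_b, stride = 1L, pad = 1L)
  s3 <- sigmoid_fwd(c3$out)
  list(out = s3$out, cache = list(c1 = c1$cache, a1 = a1$cache, u1 = u1$cache,
                                  c2 = c2$cache, a2 = a2$cache, u2 = u2$cache,
                                  c3 = c3$cache, s3 = s3$cache))
}

ae_decode_bwd <- function(p, dy, cache) {
  g <- list()
  dx <- sigmoid_bwd(dy, cache$s3)
  b3 <- conv2d_bwd(dx, p$d3_w, cache$c3); g$d3_w <- b3$dW; g$d3_b <- b3$db
  dx <- upsample2_bwd(b3$dx, cache$u2)
  dx <- elu_bwd(dx, cache$a2)
  b2 <- conv2d_bwd(dx, p$d2_w, cache$c2); g$d2_w <- b2$dW; g$d2_b <- b2$db
  dx <- upsample2_bwd(b2$dx, cache$u1)
  dx <- elu_bwd(dx, cache$a1)
  b1 <- conv2d_bwd(dx, p$d1_w, cache$c1); g$d1_w <- b1$dW; g$d1_b <- b1$db
  list(dz = b1$dx, grads = g)
}

ae_encode_bwd <- function(p, dz, cache) {
  g <- list()
  b2 <- conv2d_bwd(dz, p$e2_w, cache$c2); g$e2_w <- b2$dW; g$e2_b <- b2$db
  dx <- elu_bwd(b2$dx, cache$a1)
  b1 <- conv2d_bwd(dx, p$e1_w, cache$c1); g$e1_w <- b1$dW; g$e1_b <- b1$db
  g
}

#' Train the latent autoencoder on stimulus images
#'
#' Two stride-2 convolutions compress a `side x side x 3` image to a
#' `side/4 x side/4 x latent_c` latent (12x fewer elements at the
#' defaults); the decoder mirrors them with nearest-neighbor upsampling.
#' Trained with mean-squared reconstruction error under AdamW.
#'
#' @param images `(n, side, side, 3)` array in `[0,1]`, or a `stimulus_set`.
#' @param latent_c latent channels (default 4).
#' @param width hidden width.
#' @param epochs,batch_size,lr training settings.
#' @param holdout fraction of images kept out for the reported
#'   reconstruction error.
#' @param seed run seed.
#' @return a `latent_autoencoder`: parameters, geometry, training history,
#'   `holdout_mse` and the mean-image baseline `baseline_mse`.
#' @export
train_latent_autoencoder <- function(images, latent_c = 4L, width = 16L,
                                     epochs = 15L, batch_size = 32L, lr = 2e-3,
                                     holdout = 0.1, seed = 1L) {
  if (inherits(images, "stimulus_set")) images <- stimulus_array(images)$x
  n <- dim(images)[1]
  abort_if(n < 100, "need at least 100 images")
  side <- dim(images)[2]
  p <- with_seed(seed, autoencoder_params(side, latent_c, width))
  state <- adamw_init(p)
  hist <- numeric(0)
  with_seed(seed + 1L, {
    ho <- sample.int(n, max(1L, round(holdout * n)))
    tr_idx <- setdiff(seq_len(n), ho)
    steps <- max(1L, length(tr_idx) %/% batch_size)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      for (bs in seq_len(steps)) {
        idx <- ord[((bs - 1L) * batch_size + 1L):min(length(ord), bs * batch_size)]
        xb <- images[idx, , , , drop = FALSE]
        enc <- ae_encode_fwd(p, xb)
        dec <- ae_decode_fwd(p, enc$out)
        diff <- dec$out - xb
        loss <- mean(diff^2)
        ep_loss <- ep_loss + loss
        dd <- ae_decode_bwd(p, 2 * diff / length(diff), dec$cache)
        ge <- ae_encode_bwd(p, dd$dz, enc$cache)
        upd <- adamw_step(p, c(dd$grads, ge), state, lr, weight_decay = 1e-5,
                          decay_mask = decay_params(p))
        p <- upd$params; state <- upd$state
      }
      hist <- c(hist, ep_loss / steps)
    }
    abort_if(!is.finite(hist[length(hist)]),
             paste("autoencoder training diverged; loss history:",
                   paste(signif(hist, 3), collapse = " ")))
    xh <- images[ho, , , , drop = FALSE]
    rec <- ae_decode_fwd(p, ae_encode_fwd(p, xh)$out)$out
    holdout_mse <- mean((rec - xh)^2)
    mean_img <- apply(images[tr_idx, , , , drop = FALSE], c(2, 3, 4), mean)
    baseline_mse <- mean(sweep(xh, c(2, 3, 4), mean_img)^2)
    structure(list(params = p, side = side, latent_c = as.integer(latent_c),
                   latent_hw = side %/% 4L, width = as.integer(width),
                   history = hist, holdout_mse = holdout_mse,
                   baseline_mse = baseline_mse),
              class = "latent_autoencoder")
  })
}

#' Encode images to latents
#' @param ae a `latent_autoencoder`.
#' @param x `(n, side, side, 3)` array.
#' @return `(n, side/4, side/4, latent_c)` latent array.
#' @export
ae_encode <- function(ae, x) ae_encode_fwd(ae$params, x)$out

#' Decode latents to images
#' @param ae a `latent_autoencoder`.
#' @param z latent array.
#' @return image array in `[0,1]`.
#' @export
ae_decode <- function(ae, z) ae_decode_fwd(ae$params, z)$out
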