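# EEG-to-image reconstruction: selective fine-tuning of the conditioned
# LDM with EEG embeddings, PLMS generation, n-way top-1 evaluation and
# the inter-trial null control.

#' Bundle the reconstruction components
#' @param autoencoder a `latent_autoencoder`.
#' @param denoiser denoiser parameter list (from [train_ldm()]).
#' @param dn_config a [denoiser_config()].
#' @param schedule a [diffusion_schedule()].
#' @param latent_scale multiplicative latent normalization factor.
#' @export
ldm_bundle <- function(autoencoder, denoiser, dn_config, schedule, latent_scale) {
  structure(list(autoencoder = autoencoder, denoiser = denoiser,
                 dn_config = dn_config, schedule = schedule,
                 latent_scale = latent_scale),
            class = "ldm_bundle")
}

#' Compute scaled latents for a set of images
#' @param ae a `latent_autoencoder`.
#' @param images `(n, side, side, 3)` array.
#' @param scale existing scale, or NULL to fit `1/sd(latents)`.
#' @return list `z` (scaled latents) and `scale`.
#' @export
image_latents <- function(ae, images, scale = NULL) {
  z <- ae_encode(ae, images)
  if (is.null(scale)) scale <- 1 / stats::sd(as.vector(z))
  list(z = z * scale, scale = scale)
}

#' Fine-tune the EEG conditioning pathway of a pretrained LDM
#'
#' Joint training of the EEG encoder together with the cross-attention
#' weights and the two projectors on paired (EEG epoch, image latent)
#' data, under the double-conditioned noise-prediction objective. All
#' other denoiser weights -- the UNet convolutions and the time-embedding
#' MLP -- stay bit-identical. The encoder runs with frozen batch-norm
#' statistics during fine-tuning.
#'
#' @param encoder a trained EEGNet+ `model_handle`.
#' @param ldm an [ldm_bundle()] with a pretrained denoiser.
#' @param epochs_set `epoch_set` of training trials.
#' @param latents `(n, h, h, c)` scaled latents paired to the trials.
#' @param steps optimizer steps.
#' @param batch_size,lr training settings (desk scale uses a larger LR
#'   and fewer steps than the full-scale 5e-6 / 200-epoch recipe).
#' @param seed run seed.
#' @return list: `encoder`, `ldm` (updated), `history`, and
#'   `trainable` (names of the updated denoiser groups).
#' @export
finetune <- function(encoder, ldm, epochs_set, latents, steps = 150L,
                     batch_size = 16L, lr = 1e-3, seed = 1L) {
  abort_if(encoder$type != "eegnet_plus", "encoder must be an EEGNet+ handle")
  n <- dim(epochs_set$data)[1]
  abort_if(n != dim(latents)[1], "paired data size mismatch")
  p <- ldm$denoiser
  cfg <- ldm$dn_config
  groups <- finetune_groups()
  abort_if(length(groups) == 0, "empty trainable set")
  st_ldm <- adamw_init(p[groups])
  st_enc <- adamw_init(encoder$params)
  hist <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      idx <- sample.int(n, min(batch_size, n))
      xb <- epochs_set$data[idx, , , drop = FALSE]
      fw <- eegnet_forward(encoder, xb, training = FALSE)
      res <- diffusion_loss(latents[idx, , , , drop = FALSE], fw$embedding,
                            p, cfg, ldm$schedule, double_cond = TRUE,
                            grads = TRUE)
      hist[s] <- res$loss
      gl <- res$grads[groups]
      upd <- adamw_step(p[groups], gl, st_ldm, lr, weight_decay = 0)
      p[groups] <- upd$params; st_ldm <- upd$state
      ge <- eegnet_backward(encoder, fw$cache, dlogits = NULL,
                            dembedding = res$dy)
      upe <- adamw_step(encoder$params, ge, st_enc, lr / 2, weight_decay = 0)
      encoder$params <- upe$params; st_enc <- upe$state
    }
  })
  ldm$denoiser <- p
  list(encoder = encoder, ldm = ldm, history = hist, trainable = groups)
}

#' n-way top-1 accuracy of generated images
#'
#' For every generated image, `trials` Monte-Carlo draws each pick `n - 1`
#' distractor classes uniformly without replacement; a draw succeeds when
#' the surrogate classifier scores the true class above every distractor.
#'
#' @param images `(n_img, side, side, 3)` generated images, or a
#'   precomputed score matrix via `scores`.
#' @param true_labels 0-based class per image.
#' @param classifier a `surrogate_classifier`.
#' @param n comparison set size (n = 1 is trivially correct).
#' @param trials Monte-Carlo draws per image.
#' @param seed RNG seed.
#' @param scores optional `(n_img, k)` score matrix replacing classifier
#'   evaluation.
#' @return list: `accuracy` (mean over images and trials), `per_image`
#'   accuracy vector.
#' @export
n_way_top1 <- function(images, true_labels, classifier, n = 20L,
                       trials = 200L, seed = 1L, scores = NULL) {
  if (is.null(scores)) scores <- surrogate_scores(classifier, images)
  k <- ncol(scores)
  abort_if(n > k, "n exceeds the number of candidate classes")
  abort_if(n < 1, "n must be >= 1")
  n_img <- nrow(scores)
  per_image <- with_seed(seed, {
    vapply(seq_len(n_img), function(i) {
      truth <- true_labels[i] + 1L
      if (n == 1) return(1)
      s_true <- scores[i, truth]
      others <- setdiff(seq_len(k), truth)
      hits <- vapply(seq_len(trials), function(tr) {
        ds <- sample(others, n - 1L)
        as.numeric(s_true > max(scores[i, ds]))
      }, 0)
      mean(hits)
    }, 0)
  })
  list(accuracy = mean(per_image), per_image = per_image)
}

#' Reconstruct images from EEG embeddings and score them
#'
#' Generates `n_samples` reconstructions per trial with distinct seeds,
#' scores each with the surrogate classifier under the n-way top-1
#' protocol, and reports the best-sample and mean-over-samples accuracies.
#'
#' @param encoder fine-tuned EEGNet+ handle.
#' @param ldm fine-tuned [ldm_bundle()].
#' @param epochs_set trials to reconstruct (`epoch_set` or array).
#' @param labels 0-based true class per trial.
#' @param classifier a `surrogate_classifier`.
#' @param n_samples reconstructions per trial (default 5).
#' @param plms_steps sampling steps.
#' @param n_way comparison set size.
#' @param mc_trials Monte-Carlo draws per image.
#' @param seed base seed; sample s of trial i uses seed + 131 * i + s.
#' @return a `reconstruction_report`: `best_of` accuracy, `mean_of`
#'   accuracy, per-image matrices, the generated images of the best
#'   samples, and Monte-Carlo standard errors (over images).
#' @export
reconstruct_images <- function(encoder, ldm, epochs_set, labels, classifier,
                               n_samples = 5L, plms_steps = 25L, n_way = 20L,
                               mc_trials = 200L, seed = 1L) {
  emb <- extract_embedding(encoder, epochs_set)
  n_img <- nrow(emb)
  side <- ldm$autoencoder$side
  acc <- matrix(0, n_img, n_samples)
  best_imgs <- array(0, dim = c(n_img, side, side, 3))
  for (i in seq_len(n_img)) {
    samp_imgs <- array(0, dim = c(n_samples, side, side, 3))
    for (s in seq_len(n_samples)) {
      z <- sample_plms(ldm$denoiser, ldm$dn_config, ldm$schedule, emb[i, ],
                       steps = plms_steps, seed = seed + 131L * i + s)
      zi <- array(z / ldm$latent_scale, dim = c(1, dim(z)))
      img <- ae_decode(ldm$autoencoder, zi)
      samp_imgs[s, , , ] <- img[1, , , ]
    }
    sc <- surrogate_scores(classifier, samp_imgs)
    r <- n_way_top1(NULL, rep(labels[i], n_samples), classifier, n = n_way,
                    trials = mc_trials, seed = seed + i, scores = sc)
    acc[i, ] <- r$per_image
    best_imgs[i, , , ] <- samp_imgs[which.max(r$per_image), , , ]
  }
  best <- apply(acc, 1, max)
  mean5 <- rowMeans(acc)
  structure(list(
    best_of = mean(best), mean_of = mean(mean5),
    best_per_image = best, mean_per_image = mean5,
    best_sample_index = apply(acc, 1, which.max),
    se_best = stats::sd(best) / sqrt(n_img),
    n_images = n_img, n_way = n_way, n_samples = n_samples,
    seed = seed, best_images = best_imgs, labels = labels
  ), class = "reconstruction_report")
}

#' Inter-trial null control
#'
#' Extracts the 1 s gray-screen windows that carry no stimulus-evoked
#' signal, linearly upsamples them to the 500-sample trial length,
#' applies channel-wise z-normalization, and runs them through the same
#' encoder -> sampler -> metric pathway. Accuracy should sit at chance.
#'
#' @param rec a `raw_recording` (filtered or raw).
#' @param encoder,ldm,classifier fine-tuned components.
#' @param n_trials number of inter-trial windows to use.
#' @param labels 0-based pseudo-labels to score against (the class of the
#'   preceding stimulus by default).
#' @param interp interpolation method, `"linear"` or `"constant"`.
#' @param ... forwarded to [reconstruct_images()].
#' @return a `reconstruction_report`.
#' @export
null_control <- function(rec, encoder, ldm, classifier, n_trials = 20L,
                         labels = NULL, interp = "linear", ...) {
  spec <- attr(rec$events, "spec")
  isi_samps <- spec$step_samps - spec$stim_samps
  abort_if(isi_samps <= 0, "no inter-trial windows in this session")
  n_avail <- nrow(rec$events)
  n_trials <- min(n_trials, n_avail)
  idx <- round(seq(1, n_avail, length.out = n_trials))
  data <- array(0, dim = c(n_trials, nrow(rec$signal), spec$stim_samps))
  for (j in seq_along(idx)) {
    i <- idx[j]
    win <- rec$events$onset_sample[i] + spec$stim_samps + seq_len(isi_samps)
    seg <- rec$signal[, win, drop = FALSE]
    for (ch in seq_len(nrow(seg))) {
      data[j, ch, ] <- stats::approx(seq_len(isi_samps), seg[ch, ],
                                     n = spec$stim_samps, method = interp)$y
    }
  }
  # channel-wise z-normalization over the null set
  for (ch in seq_len(dim(data)[2])) {
    v <- data[, ch, ]
    data[, ch, ] <- (v - mean(v)) / stats::sd(as.vector(v))
  }
  if (is.null(labels)) labels <- rec$events$class_id[idx]
  ep <- new_epoch_set(data, labels, rep(TRUE, n_trials),
                      paste0(rec$session_id, "-null"), rec$fs_hz,
                      normalized = TRUE, provenance = "inter-trial upsampled")
  reconstruct_images(encoder, ldm, ep, labels, classifier, ...)
}
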