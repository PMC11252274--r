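#!/usr/bin/env Rscript
# Image reconstruction: train the EEGNet+ encoder, the latent codec and
# the conditioned denoiser; fine-tune the conditioning pathway on paired
# (EEG, image-latent) data; reconstruct held-out trials with PLMS and
# score them with the n-way top-1 protocol against the inter-trial null.

library(vepdecode)

out <- "results/subject01"
seed <- 1L
spec <- session_spec()

sess <- sort(list.files(file.path(out, "epochs"), pattern = "^S", full.names = TRUE))
eps <- lapply(sess, read_epochs)
split <- jsonlite::read_json(file.path(out, "split.json"), simplifyVector = TRUE)

# image side: codec, latents, surrogate metric classifier, LDM prior
stimuli <- generate_stimulus_images(spec, side_px = 32L,
                                    seed = derive_seed(seed, "stimuli"))
arr <- stimulus_array(stimuli)
ae <- train_latent_autoencoder(arr$x, epochs = 12L, seed = derive_seed(seed, "ae"))
lat <- image_latents(ae, arr$x)
clf <- train_surrogate(arr$x, arr$labels, seed = derive_seed(seed, "surrogate"))
dcfg <- denoiser_config(latent_hw = 8L, latent_c = 4L)
sch <- diffusion_schedule(300L)          # desk-scale schedule for the toy denoiser
ldm0 <- train_ldm(lat$z, arr$labels, dcfg, sch, steps = 1500L, lr = 2e-3,
                  seed = derive_seed(seed, "ldm"))
message(sprintf("LDM pretraining loss: %.3f", mean(tail(ldm0$history, 50))))

# EEG side: EEGNet+ encoder trained on the classification task
cfg <- eegnet_config(f1 = 8L, temporal_kernel = 32L)
enc_res <- train_classifier(build_eegnet_plus(cfg, 512L, seed = 1),
                            concat_epochs(eps[split$train]), eps[[split$val]],
                            train_config(epochs = 8L, max_lr = 1e-2, seed = 2L))
message(sprintf("EEGNet+ validation accuracy: %.1f%%",
                100 * max(enc_res$history$val_acc, na.rm = TRUE)))

# selective fine-tuning on train+val pairs
tr <- concat_epochs(eps[c(split$train, split$val)])
pair_idx <- tr$labels * spec$images_per_class + tr$image_ids + 1L
bundle <- ldm_bundle(ae, ldm0$params, dcfg, sch, lat$scale)
ft <- finetune(enc_res$handle, bundle, tr, lat$z[pair_idx, , , , drop = FALSE],
               steps = 400L, lr = 1e-3, seed = derive_seed(seed, "finetune"))
message(sprintf("fine-tuning loss %.3f -> %.3f",
                mean(head(ft$history, 30)), mean(tail(ft$history, 30))))

# reconstruct one test trial per class, five samples each
test <- eps[[split$test]]
sel <- unlist(lapply(0:(spec$n_classes - 1L),
                     function(c) which(test$labels == c)[1]))
rep <- reconstruct_images(ft$encoder, ft$ldm, test$data[sel, , , drop = FALSE],
                          test$labels[sel], clf, n_samples = 5L,
                          plms_steps = 20L, n_way = 20L, mc_trials = 500L,
                          seed = derive_seed(seed, "recon"))
message(sprintf("20-way top-1: best-of-5 %.1f%%, mean-of-5 %.1f%% (chance 5%%)",
                100 * rep$best_of, 100 * rep$mean_of))

# inter-trial null control on the raw test session
rec_test <- read_session(file.path(out, "sessions",
                                   paste0(test$session_id, ".edf")))
nullr <- null_control(rec_test, ft$encoder, ft$ldm, clf, n_trials = 20L,
                      n_samples = 5L, plms_steps = 20L, n_way = 20L,
                      mc_trials = 500L, seed = derive_seed(seed, "null"))
message(sprintf("null control: mean-of-5 %.1f%% (chance 5%%; best-of-5 %.1f%% reflects max-selection bias)",
                100 * nullr$mean_of, 100 * nullr$best_of))

# does classifier correctness predict reconstruction quality?
logits <- predict_logits(ft$encoder, test$data[sel, , , drop = FALSE])
correct <- as.numeric(max.col(logits) - 1L == test$labels[sel])
r_pb <- if (length(unique(correct)) > 1) {
  point_biserial(correct, rep$best_per_image)
} else NA_real_

dir.create(file.path(out, "reconstruction"), showWarnings = FALSE)
jsonlite::write_json(list(best_of = rep$best_of, mean_of = rep$mean_of,
                          null_mean_of = nullr$mean_of,
                          null_best_of = nullr$best_of,
                          point_biserial = r_pb, n_way = 20L,
                          per_image_best = rep$best_per_image),
                     file.path(out, "reconstruction", "report.json"),
                     auto_unbox = TRUE, digits = NA)
for (i in seq_along(sel)) {
  png::writePNG(rep$best_images[i, , , ],
                file.path(out, "reconstruction", sprintf("best_class%02d.png", i - 1L)))
}
write.csv(data.frame(image_id = seq_along(sel) - 1L, class_id = rep$labels,
                     sample_index = rep$best_sample_index, seed = rep$seed),
          file.path(out, "reconstruction", "manifest.csv"), row.names = FALSE)
message("wrote reconstruction report and best-sample images")
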