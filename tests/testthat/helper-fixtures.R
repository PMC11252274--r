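# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small session geometry used by cheap tests
tiny_spec <- function(n_classes = 4L, images_per_class = 5L) {
  session_spec(n_classes, images_per_class)
}

tiny_session <- function() {
  fixture("tiny_session", function() {
    spec <- tiny_spec()
    model <- vep_model(spec, snr = 2)
    ev <- make_session_events(spec, seed = 11)
    list(spec = spec, model = model, events = ev,
         rec = synthesize_recording(ev, model, seed = 12, session_id = "T01"))
  })
}

# tiny EEGNet geometry for gradient checks
grad_config <- function() {
  eegnet_config(f1 = 2L, depth_multiplier = 2L, temporal_kernel = 5L,
                sep_kernel = 3L, pool1 = 2L, pool2 = 2L, dropout_p = 0,
                n_channels = 4L, n_samples = 12L, n_classes = 3L)
}

# The full toy reconstruction system (stimuli, codec, surrogate metric,
# pretrained LDM, trained encoder, fine-tuned conditioning) at the scale
# used for the end-to-end properties. Built once; several test files and
# the acceptance suite share it.
toy_system <- function() {
  fixture("toy_system", function() {
    spec <- session_spec(20L, 30L)
    set <- generate_stimulus_images(spec, side_px = 32L, seed = 7)
    arr <- stimulus_array(set)
    clf <- train_surrogate(arr$x, arr$labels, seed = 2)
    ae <- train_latent_autoencoder(arr$x, epochs = 12L, seed = 1)
    lat <- image_latents(ae, arr$x)
    dcfg <- denoiser_config(latent_hw = 8L, latent_c = 4L)
    sch <- diffusion_schedule(300L)
    ldm0 <- train_ldm(lat$z, arr$labels, dcfg, sch, steps = 1500L,
                      lr = 2e-3, seed = 3)

    model <- vep_model(spec, snr = 3)
    sess <- lapply(1:5, function(s) {
      ev <- make_session_events(spec, seed = 20 + s)
      synthesize_recording(ev, model, seed = 120 + s,
                           session_id = sprintf("S%02d", s))
    })
    eps <- lapply(sess, preprocess_session)
    tr <- concat_epochs(eps[1:3])
    enc0 <- build_eegnet_plus(eegnet_config(f1 = 8L, temporal_kernel = 32L),
                              512L, seed = 1)
    enc_res <- train_classifier(enc0, tr, eps[[4]],
                                train_config(epochs = 8L, max_lr = 1e-2, seed = 4))
    pair_idx <- tr$labels * spec$images_per_class + tr$image_ids + 1L
    bundle <- ldm_bundle(ae, ldm0$params, dcfg, sch, lat$scale)
    ft <- finetune(enc_res$handle, bundle, tr,
                   lat$z[pair_idx, , , , drop = FALSE],
                   steps = 400L, lr = 2e-3, seed = 5)
    list(spec = spec, set = set, arr = arr, clf = clf, ae = ae, lat = lat,
         dcfg = dcfg, sch = sch, ldm0 = ldm0, model = model,
         sessions = sess, epochs = eps, encoder0 = enc_res$handle,
         pretrained = bundle, ft = ft)
  })
}
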