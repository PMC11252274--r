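# End-to-end orchestration: simulate -> preprocess -> train -> evaluate ->
# encode -> finetune -> reconstruct -> report, with persisted artifacts
# and stage-level resumability.

#' Generic weight persistence (names/dims JSON + double blob)
#' @param params named list of numeric arrays.
#' @param dir output directory.
#' @export
write_weights <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(params, function(p) as.integer(dim(p) %||% length(p)))
  jsonlite::write_json(meta, file.path(dir, "weights.json"), auto_unbox = FALSE)
  con <- file(file.path(dir, "weights.bin"), "wb")
  for (p in params) writeBin(as.numeric(p), con, size = 8, endian = "little")
  close(con)
  invisible(dir)
}

#' Load weights written by [write_weights()]
#' @param dir directory holding weights.json / weights.bin.
#' @export
read_weights <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  out <- lapply(meta, function(d) {
    v <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
    if (length(d) > 1) array(v, dim = d) else v
  })
  names(out) <- names(meta)
  out
}

#' Save a model checkpoint (config JSON + weight blobs + inventory CSV)
#' @param handle a `model_handle`.
#' @param dir checkpoint directory.
#' @export
save_model_handle <- function(handle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(type = handle$type, config = unclass(handle$config),
                            embed_dim = handle$embed_dim),
                       file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  write_weights(handle$params, file.path(dir, "params"))
  write_weights(handle$running, file.path(dir, "running"))
  utils::write.csv(parameter_inventory(handle), file.path(dir, "inventory.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint written by [save_model_handle()]
#' @param dir checkpoint directory.
#' @export
load_model_handle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- do.call(eegnet_config, meta$config[setdiff(names(meta$config),
                                                    c("f2", "t_out"))])
  h <- new_model_handle(meta$type, read_weights(file.path(dir, "params")),
                        read_weights(file.path(dir, "running")), cfg,
                        embed_dim = meta$embed_dim)
  h$mode <- "eval"
  h
}

pipeline_fields <- c(
  "out_dir", "seed", "n_sessions", "n_classes", "images_per_class",
  "stim_dur_s", "isi_s", "fs_hz", "snr", "side_px",
  "f1", "depth_multiplier", "temporal_kernel", "dropout_p", "pool_mode",
  "epochs", "max_lr", "batch_size",
  "ae_epochs", "ldm_steps", "finetune_steps", "plms_steps",
  "n_recon_images", "n_samples", "n_way", "mc_trials")

#' Pipeline configuration
#'
#' All knobs of the end-to-end run in one validated object. Unknown
#' fields are rejected.
#'
#' @param out_dir artifact directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param ... overrides of the defaults (see `vepdecode:::pipeline_fields`).
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_sessions = 3L, n_classes = 20L, images_per_class = 30L,
              stim_dur_s = 2.0, isi_s = 1.0, fs_hz = 250L, snr = 3,
              side_px = 32L,
              f1 = 8L, depth_multiplier = 2L, temporal_kernel = 32L,
              dropout_p = 0.25, pool_mode = "max",
              epochs = 8L, max_lr = 1e-2, batch_size = 64L,
              ae_epochs = 12L, ldm_steps = 300L, finetune_steps = 150L,
              plms_steps = 20L, n_recon_images = 20L, n_samples = 5L,
              n_way = 20L, mc_trials = 200L)
  ov <- list(...)
  unknown <- setdiff(names(ov), pipeline_fields)
  abort_if(length(unknown) > 0,
           paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  abort_if(cfg$n_sessions < 3, "need n_sessions >= 3 for the hold-out split")
  # construct sub-configs now so validation errors precede any compute
  cfg$session <- session_spec(cfg$n_classes, cfg$images_per_class,
                              cfg$stim_dur_s, cfg$isi_s, cfg$fs_hz)
  cfg$eegnet <- eegnet_config(f1 = cfg$f1, depth_multiplier = cfg$depth_multiplier,
                              temporal_kernel = cfg$temporal_kernel,
                              dropout_p = cfg$dropout_p, pool_mode = cfg$pool_mode,
                              n_samples = cfg$session$stim_samps,
                              n_classes = cfg$n_classes)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  abort_if(is.null(y$out_dir), "config must set out_dir")
  do.call(pipeline_config, y)
}

pipeline_stages <- c("simulate", "preprocess", "train", "evaluate",
                     "encode", "finetune", "reconstruct", "report")

need_artifact <- function(path, stage) {
  abort_if(!file.exists(path),
           sprintf("missing artifact %s: rerun stage '%s'", path, stage))
}

#' Run the decoding pipeline end to end
#'
#' Executes the stages in order, persisting every stage's outputs under
#' `config$out_dir` together with the effective configuration and seeds.
#' With `from`, earlier stages are skipped and their artifacts must
#' already exist (an informative error names the stage to rerun).
#'
#' @param config a [pipeline_config()].
#' @param from first stage to execute.
#' @param verbose log stage progress.
#' @return the artifact directory, invisibly.
#' @export
run_pipeline <- function(config, from = "simulate", verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  abort_if(!from %in% pipeline_stages, paste("unknown stage:", from))
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config)[pipeline_fields], file.path(od, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  run <- function(stage) match(stage, pipeline_stages) >= match(from, pipeline_stages)
  log <- function(...) if (verbose) message(sprintf("[%s] %s",
                                                    format(Sys.time(), "%H:%M:%S"),
                                                    sprintf(...)))
  spec <- config$session

  sess_ids <- sprintf("S%02d", seq_len(config$n_sessions))
  if (run("simulate")) {
    log("simulate: %d sessions, snr=%g", config$n_sessions, config$snr)
    model <- vep_model(spec, snr = config$snr,
                       model_seed = derive_seed(config$seed, "vep-model"))
    for (i in seq_along(sess_ids)) {
      ev <- make_session_events(spec, derive_seed(config$seed, paste0("events", i)))
      rec <- synthesize_recording(ev, model, derive_seed(config$seed, paste0("signal", i)),
                                  session_id = sess_ids[i])
      write_session(rec, file.path(od, "sessions"))
    }
    set <- generate_stimulus_images(spec, config$side_px,
                                    derive_seed(config$seed, "stimuli"))
    write_stimulus_images(set, file.path(od, "stimuli"))
  }

  if (run("preprocess")) {
    log("preprocess")
    for (sid in sess_ids) {
      edf <- file.path(od, "sessions", paste0(sid, ".edf"))
      need_artifact(edf, "simulate")
      ep <- preprocess_session(read_session(edf))
      write_epochs(ep, file.path(od, "epochs", sid))
    }
    eps <- lapply(sess_ids, function(s) read_epochs(file.path(od, "epochs", s)))
    utils::write.csv(drop_report(eps), file.path(od, "epochs", "drop_report.csv"),
                     row.names = FALSE)
  }

  tcfg <- train_config(max_lr = config$max_lr, epochs = config$epochs,
                       batch_size = config$batch_size,
                       seed = derive_seed(config$seed, "train"))
  load_eps <- function() {
    lapply(sess_ids, function(s) {
      need_artifact(file.path(od, "epochs", s, "header.json"), "preprocess")
      read_epochs(file.path(od, "epochs", s))
    })
  }

  if (run("train")) {
    log("train classifier")
    eps <- load_eps()
    split <- make_split(eps)
    jsonlite::write_json(split, file.path(od, "split.json"), auto_unbox = TRUE)
    res <- train_classifier(build_eegnet(config$eegnet,
                                         derive_seed(config$seed, "init")),
                            concat_epochs(eps[split$train]), eps[[split$val]], tcfg)
    save_model_handle(res$handle, file.path(od, "classifier"))
    utils::write.csv(res$history, file.path(od, "classifier", "history.csv"),
                     row.names = FALSE)
  }

  if (run("evaluate")) {
    log("evaluate")
    need_artifact(file.path(od, "classifier", "model.json"), "train")
    need_artifact(file.path(od, "split.json"), "train")
    eps <- load_eps()
    split <- jsonlite::read_json(file.path(od, "split.json"), simplifyVector = TRUE)
    h <- load_model_handle(file.path(od, "classifier"))
    rep <- evaluate(h, eps[[split$test]])
    jsonlite::write_json(list(accuracy = rep$accuracy, per_class = rep$per_class,
                              n = rep$n, seed = config$seed),
                         file.path(od, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(rep$confusion, file.path(od, "confusion.csv"))
  }

  if (run("encode")) {
    log("encode: train EEGNet+ and extract embeddings")
    eps <- load_eps()
    need_artifact(file.path(od, "split.json"), "train")
    split <- jsonlite::read_json(file.path(od, "split.json"), simplifyVector = TRUE)
    res <- train_classifier(build_eegnet_plus(config$eegnet, 512L,
                                              derive_seed(config$seed, "init+")),
                            concat_epochs(eps[split$train]), eps[[split$val]], tcfg)
    save_model_handle(res$handle, file.path(od, "encoder"))
  }

  if (run("finetune")) {
    log("finetune: autoencoder + LDM + conditioning pathway")
    need_artifact(file.path(od, "encoder", "model.json"), "encode")
    need_artifact(file.path(od, "stimuli", "manifest.csv"), "simulate")
    eps <- load_eps()
    split <- jsonlite::read_json(file.path(od, "split.json"), simplifyVector = TRUE)
    set <- generate_stimulus_images(spec, config$side_px,
                                    derive_seed(config$seed, "stimuli"))
    arr <- stimulus_array(set)
    ae <- train_latent_autoencoder(arr$x, epochs = config$ae_epochs,
                                   seed = derive_seed(config$seed, "ae"))
    lat <- image_latents(ae, arr$x)
    dcfg <- denoiser_config(latent_hw = config$side_px %/% 4L)
    sch <- diffusion_schedule()
    ldm0 <- train_ldm(lat$z, arr$labels, dcfg, sch, steps = config$ldm_steps,
                      seed = derive_seed(config$seed, "ldm"))
    enc <- load_model_handle(file.path(od, "encoder"))
    tr <- concat_epochs(eps[c(split$train, split$val)])
    # pair each trial with the latent of its presented image
    pair_idx <- tr$labels * spec$images_per_class + tr$image_ids + 1L
    bundle <- ldm_bundle(ae, ldm0$params, dcfg, sch, lat$scale)
    ft <- finetune(enc, bundle, tr, lat$z[pair_idx, , , , drop = FALSE],
                   steps = config$finetune_steps,
                   seed = derive_seed(config$seed, "finetune"))
    save_model_handle(ft$encoder, file.path(od, "encoder_ft"))
    write_weights(ft$ldm$denoiser, file.path(od, "ldm", "denoiser"))
    write_weights(ae$params, file.path(od, "ldm", "autoencoder"))
    jsonlite::write_json(list(latent_scale = lat$scale,
                              dn_config = unclass(dcfg),
                              trainable = ft$trainable,
                              final_loss = mean(utils::tail(ft$history, 20))),
                         file.path(od, "ldm", "meta.json"), auto_unbox = TRUE, digits = NA)
  }

  if (run("reconstruct")) {
    log("reconstruct: PLMS sampling + n-way top-1")
    need_artifact(file.path(od, "ldm", "meta.json"), "finetune")
    eps <- load_eps()
    split <- jsonlite::read_json(file.path(od, "split.json"), simplifyVector = TRUE)
    meta <- jsonlite::read_json(file.path(od, "ldm", "meta.json"), simplifyVector = TRUE)
    dcfg <- do.call(denoiser_config, meta$dn_config[setdiff(names(meta$dn_config),
                                                            c("width2", "token_in"))])
    set <- generate_stimulus_images(spec, config$side_px,
                                    derive_seed(config$seed, "stimuli"))
    arr <- stimulus_array(set)
    clf <- train_surrogate(arr$x, arr$labels,
                           seed = derive_seed(config$seed, "surrogate"))
    ae <- structure(list(params = read_weights(file.path(od, "ldm", "autoencoder")),
                         side = config$side_px, latent_c = dcfg$latent_c,
                         latent_hw = dcfg$latent_hw), class = "latent_autoencoder")
    bundle <- ldm_bundle(ae, read_weights(file.path(od, "ldm", "denoiser")),
                         dcfg, diffusion_schedule(), meta$latent_scale)
    enc <- load_model_handle(file.path(od, "encoder_ft"))
    test <- eps[[split$test]]
    n_img <- min(config$n_recon_images, dim(test$data)[1])
    sel <- round(seq(1, dim(test$data)[1], length.out = n_img))
    rep <- reconstruct_images(enc, bundle, test$data[sel, , , drop = FALSE],
                              test$labels[sel], clf,
                              n_samples = config$n_samples,
                              plms_steps = config$plms_steps,
                              n_way = config$n_way, mc_trials = config$mc_trials,
                              seed = derive_seed(config$seed, "recon"))
    dir.create(file.path(od, "reconstruction"), showWarnings = FALSE)
    for (i in seq_len(n_img)) {
      png::writePNG(rep$best_images[i, , , ],
                    file.path(od, "reconstruction", sprintf("best_%03d.png", i)))
    }
    utils::write.csv(data.frame(image_id = seq_len(n_img) - 1L,
                                class_id = rep$labels,
                                sample_index = rep$best_sample_index,
                                seed = rep$seed),
                     file.path(od, "reconstruction", "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(best_of = rep$best_of, mean_of = rep$mean_of,
                              per_image_best = rep$best_per_image,
                              n_way = rep$n_way, n_images = rep$n_images,
                              seed = config$seed),
                         file.path(od, "reconstruction", "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (run("report")) {
    log("report")
    need_artifact(file.path(od, "evaluation.json"), "evaluate")
    need_artifact(file.path(od, "reconstruction", "report.json"), "reconstruct")
    ev <- jsonlite::read_json(file.path(od, "evaluation.json"), simplifyVector = TRUE)
    rc <- jsonlite::read_json(file.path(od, "reconstruction", "report.json"),
                              simplifyVector = TRUE)
    summary <- list(seed = config$seed,
                    config_hash = sum(utf8ToInt(jsonlite::toJSON(
                      unclass(config)[pipeline_fields], auto_unbox = TRUE))),
                    classification_accuracy_pct = ev$accuracy,
                    reconstruction_best_of = rc$best_of,
                    reconstruction_mean_of = rc$mean_of,
                    chance_level = 1 / config$n_way)
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(od)
}
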