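# EEGNet: compact depthwise-separable CNN for single-trial EEG, and its
# encoder variant (EEGNet+) with a 512-d embedding head.

#' EEGNet configuration
#'
#' The default values reproduce the best configuration for 8-channel,
#' 500-sample VEP trials: 64 temporal filters of kernel length 64, depth
#' multiplier 2 (128 separable maps), max pooling over 4 then 8 samples
#' and dropout 0.25 -- a network of 62,612 trainable parameters.
#'
#' @param f1 number of temporal filters.
#' @param depth_multiplier spatial filters learned per temporal filter.
#' @param temporal_kernel temporal kernel length in samples.
#' @param sep_kernel depthwise kernel length of the separable block.
#' @param pool1,pool2 pooling widths of the two blocks.
#' @param pool_mode "max" or "mean".
#' @param dropout_p dropout probability.
#' @param n_channels,n_samples,n_classes input/output geometry.
#' @return an `eegnet_config`.
#' @export
eegnet_config <- function(f1 = 64L, depth_multiplier = 2L, temporal_kernel = 64L,
                          sep_kernel = 16L, pool1 = 4L, pool2 = 8L,
                          pool_mode = "max", dropout_p = 0.25,
                          n_channels = 8L, n_samples = 500L, n_classes = 20L) {
  abort_if(!(dropout_p >= 0 && dropout_p < 1), "dropout_p must be in [0,1)")
  t1 <- n_samples %/% pool1
  t2 <- t1 %/% pool2
  abort_if(t2 < 1, "pool sizes reduce the time axis below 1")
  structure(list(f1 = as.integer(f1), depth_multiplier = as.integer(depth_multiplier),
                 f2 = as.integer(f1 * depth_multiplier),
                 temporal_kernel = as.integer(temporal_kernel),
                 sep_kernel = as.integer(sep_kernel),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 pool_mode = pool_mode, dropout_p = dropout_p,
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 t_out = as.integer(t2)),
            class = "eegnet_config")
}

eegnet_backbone_params <- function(cfg) {
  with(cfg, list(
    conv1_w = he_init(c(f1, temporal_kernel), temporal_kernel),
    bn1_g = rep(1, f1), bn1_b = rep(0, f1),
    dw_w = he_init(c(f1, depth_multiplier, n_channels), n_channels),
    bn2_g = rep(1, f2), bn2_b = rep(0, f2),
    sep_dw_w = he_init(c(f2, sep_kernel), sep_kernel),
    sep_pw_w = he_init(c(f2, f2), f2),
    bn3_g = rep(1, f2), bn3_b = rep(0, f2)
  ))
}

eegnet_running <- function(cfg) {
  with(cfg, list(bn1_m = rep(0, f1), bn1_v = rep(1, f1),
                 bn2_m = rep(0, f2), bn2_v = rep(1, f2),
                 bn3_m = rep(0, f2), bn3_v = rep(1, f2)))
}

new_model_handle <- function(type, params, running, config, embed_dim = NULL) {
  h <- structure(list(type = type, params = params, running = running,
                      config = config, mode = "train", embed_dim = embed_dim),
                 class = "model_handle")
  h
}

#' Build an EEGNet classifier
#'
#' Blocks: temporal conv (F1 x kernel, shared across channels) -> BN ->
#' depthwise spatial conv over all 8 channels -> BN -> ELU -> pool ->
#' dropout -> separable conv (depthwise temporal + pointwise) -> BN ->
#' ELU -> pool -> dropout -> flatten -> linear classifier. Convolutions
#' are bias-free (batch-norm follows each); the classifier carries a bias.
#'
#' @param config an [eegnet_config()].
#' @param seed seed for weight initialization.
#' @return a `model_handle` mapping `(batch, 8, 500)` to `(batch, n_classes)`
#'   logits.
#' @export
build_eegnet <- function(config = eegnet_config(), seed = 1) {
  params <- with_seed(seed, {
    p <- eegnet_backbone_params(config)
    nf <- config$f2 * config$t_out
    p$fc_w <- he_init(c(nf, config$n_classes), nf)
    p$fc_b <- rep(0, config$n_classes)
    p
  })
  new_model_handle("eegnet", params, eegnet_running(config), config)
}

#' Build an EEGNet+ encoder/classifier
#'
#' Same backbone as [build_eegnet()], with the classifier head replaced by
#' two linear layers: the first maps the flattened features to a 512-d
#' embedding, the second maps the (ELU-activated) embedding to the class
#' logits. Dropping the final layer turns the model into the EEG encoder.
#'
#' @param config an [eegnet_config()].
#' @param embed_dim embedding width (default 512).
#' @param seed seed for weight initialization.
#' @return a `model_handle`.
#' @export
build_eegnet_plus <- function(config = eegnet_config(), embed_dim = 512L, seed = 1) {
  abort_if(embed_dim <= 0, "embed_dim must be positive")
  params <- with_seed(seed, {
    p <- eegnet_backbone_params(config)
    nf <- config$f2 * config$t_out
    p$fc1_w <- he_init(c(nf, embed_dim), nf)
    p$fc1_b <- rep(0, embed_dim)
    p$fc2_w <- he_init(c(embed_dim, config$n_classes), embed_dim)
    p$fc2_b <- rep(0, config$n_classes)
    p
  })
  new_model_handle("eegnet_plus", params, eegnet_running(config),
                   config, embed_dim = as.integer(embed_dim))
}

#' Per-layer trainable parameter inventory
#' @param handle a `model_handle`.
#' @return data.frame with `layer` and `count`; counts sum to the total
#'   trainable parameter number.
#' @export
parameter_inventory <- function(handle) {
  stopifnot(inherits(handle, "model_handle"))
  df <- data.frame(layer = names(handle$params),
                   count = vapply(handle$params, length, 0L))
  rownames(df) <- NULL
  df
}

#' Total trainable parameter count
#' @param handle a `model_handle`.
#' @export
n_parameters <- function(handle) sum(parameter_inventory(handle)$count)

# full forward pass; training toggles BN batch statistics and dropout.
# Layouts: (b, C, T) in -> (b, C, T, F1) -> (b, T, F2) -> ... -> flatten.
eegnet_forward <- function(handle, x, training = FALSE) {
  p <- handle$params; r <- handle$running; cfg <- handle$config
  cache <- list()
  s <- conv_temporal_fwd(x, p$conv1_w); cache$c1 <- s$cache
  b <- bn_fwd(s$out, p$bn1_g, p$bn1_b, r$bn1_m, r$bn1_v, training)
  r$bn1_m <- b$run_mean; r$bn1_v <- b$run_var; cache$bn1 <- b$cache
  s <- depthwise_spatial_fwd(b$out, p$dw_w); cache$dw <- s$cache
  b <- bn_fwd(s$out, p$bn2_g, p$bn2_b, r$bn2_m, r$bn2_v, training)
  r$bn2_m <- b$run_mean; r$bn2_v <- b$run_var; cache$bn2 <- b$cache
  a <- elu_fwd(b$out); cache$elu1 <- a$cache
  pl <- pool_time_fwd(a$out, cfg$pool1, cfg$pool_mode); cache$pool1 <- pl$cache
  dr <- dropout_fwd(pl$out, cfg$dropout_p, training); cache$drop1 <- dr$cache
  s <- depthwise_temporal_fwd(dr$out, p$sep_dw_w); cache$sdw <- s$cache
  s2 <- pointwise_fwd(s$out, p$sep_pw_w); cache$spw <- s2$cache
  b <- bn_fwd(s2$out, p$bn3_g, p$bn3_b, r$bn3_m, r$bn3_v, training)
  r$bn3_m <- b$run_mean; r$bn3_v <- b$run_var; cache$bn3 <- b$cache
  a <- elu_fwd(b$out); cache$elu2 <- a$cache
  pl <- pool_time_fwd(a$out, cfg$pool2, cfg$pool_mode); cache$pool2 <- pl$cache
  dr <- dropout_fwd(pl$out, cfg$dropout_p, training); cache$drop2 <- dr$cache
  fm <- dr$out
  dims_feat <- dim(fm)
  dim(fm) <- c(dims_feat[1], dims_feat[2] * dims_feat[3])
  cache$dims_feat <- dims_feat
  if (handle$type == "eegnet") {
    d <- dense_fwd(fm, p$fc_w, p$fc_b); cache$fc <- d$cache
    logits <- d$out
    embedding <- NULL
  } else {
    d1 <- dense_fwd(fm, p$fc1_w, p$fc1_b); cache$fc1 <- d1$cache
    embedding <- d1$out
    a3 <- elu_fwd(embedding); cache$elu3 <- a3$cache
    d2 <- dense_fwd(a3$out, p$fc2_w, p$fc2_b); cache$fc2 <- d2$cache
    logits <- d2$out
  }
  list(logits = logits, embedding = embedding, cache = cache, running = r)
}

# backward from dlogits (and optionally an extra gradient on the embedding)
eegnet_backward <- function(handle, cache, dlogits, dembedding = NULL) {
  p <- handle$params; cfg <- handle$config
  g <- list()
  if (handle$type == "eegnet") {
    d <- dense_bwd(dlogits, p$fc_w, cache$fc)
    g$fc_w <- d$dW; g$fc_b <- d$db
    dfm <- d$dx
  } else {
    if (is.null(dlogits)) {
      # embedding-only objective (e.g. diffusion fine-tuning)
      demb <- dembedding
    } else {
      d2 <- dense_bwd(dlogits, p$fc2_w, cache$fc2)
      g$fc2_w <- d2$dW; g$fc2_b <- d2$db
      demb <- elu_bwd(d2$dx, cache$elu3)
      if (!is.null(dembedding)) demb <- demb + dembedding
    }
    d1 <- dense_bwd(demb, p$fc1_w, cache$fc1)
    g$fc1_w <- d1$dW; g$fc1_b <- d1$db
    dfm <- d1$dx
  }
  dfeat <- dfm
  dim(dfeat) <- cache$dims_feat
  dx <- dropout_bwd(dfeat, cache$drop2)
  dx <- pool_time_bwd(dx, cache$pool2)
  dx <- elu_bwd(dx, cache$elu2)
  b <- bn_bwd(dx, p$bn3_g, cache$bn3)
  g$bn3_g <- b$dgamma; g$bn3_b <- b$dbeta
  s2 <- pointwise_bwd(b$dx, p$sep_pw_w, cache$spw)
  g$sep_pw_w <- s2$dW
  s <- depthwise_temporal_bwd(s2$dx, p$sep_dw_w, cache$sdw)
  g$sep_dw_w <- s$dW
  dx <- dropout_bwd(s$dx, cache$drop1)
  dx <- pool_time_bwd(dx, cache$pool1)
  dx <- elu_bwd(dx, cache$elu1)
  b <- bn_bwd(dx, p$bn2_g, cache$bn2)
  g$bn2_g <- b$dgamma; g$bn2_b <- b$dbeta
  dw <- depthwise_spatial_bwd(b$dx, p$dw_w, cache$dw)
  g$dw_w <- dw$dW
  b <- bn_bwd(dw$dx, p$bn1_g, cache$bn1)
  g$bn1_g <- b$dgamma; g$bn1_b <- b$dbeta
  c1 <- conv_temporal_bwd(b$dx, p$conv1_w, cache$c1)
  g$conv1_w <- c1$dW
  g
}

#' Class logits / probabilities in evaluation mode
#' @param handle a trained `model_handle`.
#' @param x `(batch, channels, samples)` array, or an `epoch_set`.
#' @param batch_size forward chunk size.
#' @return matrix `(batch, n_classes)` of logits.
#' @export
predict_logits <- function(handle, x, batch_size = 256L) {
  if (inherits(x, "epoch_set")) x <- x$data
  n <- dim(x)[1]
  out <- matrix(0, n, handle$config$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    out[s:e, ] <- eegnet_forward(handle, x[s:e, , , drop = FALSE], training = FALSE)$logits
  }
  out
}

#' Extract 512-d embeddings from an EEGNet+ encoder
#'
#' Runs the backbone plus the first (embedding) linear layer in evaluation
#' mode; the final classification layer is not applied.
#'
#' @param handle a `model_handle` built by [build_eegnet_plus()].
#' @param epochs an `epoch_set` or a `(batch, channels, samples)` array.
#' @param batch_size forward chunk size.
#' @return matrix `(n_trials, embed_dim)`.
#' @export
extract_embedding <- function(handle, epochs, batch_size = 256L) {
  abort_if(handle$type != "eegnet_plus", "handle is not an EEGNet+ encoder")
  x <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  n <- dim(x)[1]
  out <- matrix(0, n, handle$embed_dim)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    out[s:e, ] <- eegnet_forward(handle, x[s:e, , , drop = FALSE], training = FALSE)$embedding
  }
  out
}
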