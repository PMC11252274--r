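# Toy double-conditioned latent diffusion: a 2-level UNet denoiser with
# one cross-attention resolution, conditioned on 512-d EEG embeddings via
# a token projector (cross-attention pathway) and a time-embedding
# projector (time-step pathway), trained with the noise-prediction
# objective and sampled with the pseudo linear multi-step (PLMS) method.

#' Diffusion noise schedule
#'
#' Linear beta schedule; `alpha_bar[t]` is the cumulative signal fraction
#' after `t` forward steps, strictly decreasing in `(0, 1]`.
#'
#' @param T_steps number of forward noise steps.
#' @param beta_start,beta_end endpoints of the linear beta ramp.
#' @return a `diffusion_schedule` with `beta`, `alpha_bar`, `T_steps`.
#' @export
diffusion_schedule <- function(T_steps = 1000L, beta_start = 1e-4, beta_end = 2e-2) {
  beta <- seq(beta_start, beta_end, length.out = T_steps)
  ab <- cumprod(1 - beta)
  abort_if(any(diff(ab) >= 0) || any(ab <= 0) || any(ab > 1),
           "alpha_bar must be strictly decreasing in (0,1]")
  structure(list(beta = beta, alpha_bar = ab, T_steps = as.integer(T_steps)),
            class = "diffusion_schedule")
}

#' Scaled dot-product cross-attention
#'
#' `Softmax(Q K' / sqrt(d_k)) V` with `Q = phi W_q`, `K = ctx W_k`,
#' `V = ctx W_v`: queries come from an intermediate feature map of the
#' denoiser, keys and values from the projected conditioning tokens.
#'
#' @param phi query source, `(n_query, d)` matrix.
#' @param ctx context tokens, `(M, d_tau)` matrix.
#' @param w_q `(d, d_k)`, `w_k `(d_tau, d_k)`, `w_v` `(d_tau, d_v)`
#'   projection matrices.
#' @param w_k,w_v see `w_q`.
#' @return list with `out` `(n_query, d_v)` and the attention `weights`
#'   `(n_query, M)` (rows sum to 1).
#' @export
cross_attention <- function(phi, ctx, w_q, w_k, w_v) {
  abort_if(ncol(phi) != nrow(w_q), "query dimension mismatch")
  abort_if(ncol(ctx) != nrow(w_k) || ncol(ctx) != nrow(w_v), "context dimension mismatch")
  abort_if(ncol(w_q) != ncol(w_k), "key/query width mismatch")
  q <- phi %*% w_q
  k <- ctx %*% w_k
  v <- ctx %*% w_v
  s <- tcrossprod(q, k) / sqrt(ncol(w_q))
  a <- softmax_rows(s)
  list(out = a %*% v, weights = a)
}

# forward + cache for backprop (single batch item handled by caller loop)
attn_fwd <- function(phi, ctx, w_q, w_k, w_v, w_o) {
  q <- phi %*% w_q; k <- ctx %*% w_k; v <- ctx %*% w_v
  s <- tcrossprod(q, k) / sqrt(ncol(w_q))
  a <- softmax_rows(s)
  o <- a %*% v
  list(out = o %*% w_o,
       cache = list(phi = phi, ctx = ctx, q = q, k = k, v = v, a = a, o = o))
}

attn_bwd <- function(dout, w_q, w_k, w_v, w_o, cache) {
  dk_scale <- 1 / sqrt(ncol(w_q))
  do_ <- tcrossprod(dout, w_o)
  dwo <- crossprod(cache$o, dout)
  dv <- crossprod(cache$a, do_)
  da <- tcrossprod(do_, cache$v)
  ds <- cache$a * (da - rowSums(da * cache$a))      # softmax jacobian
  dq <- ds %*% cache$k * dk_scale
  dkm <- crossprod(ds, cache$q) * dk_scale
  list(dphi = tcrossprod(dq, w_q),
       dctx = tcrossprod(dkm, w_k) + tcrossprod(dv, w_v),
       dwq = crossprod(cache$phi, dq),
       dwk = crossprod(cache$ctx, dkm),
       dwv = crossprod(cache$ctx, dv),
       dwo = dwo)
}

# sinusoidal time embedding, (length(t), d) with d even
time_embedding <- function(t, d) {
  half <- d %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1L) / half)
  ang <- outer(t, freq)
  cbind(sin(ang), cos(ang))
}

#' Denoiser (conditioned UNet) configuration
#' @param latent_hw latent spatial side.
#' @param latent_c latent channels.
#' @param width base channel width (doubled after downsampling).
#' @param d_t time-embedding dimension.
#' @param d_tau token depth after the 1x1 convolution projector.
#' @param d_k attention key width.
#' @param m_tokens number of conditioning tokens the 512-d embedding is
#'   reshaped into (adjustable).
#' @param embed_dim conditioning embedding width.
#' @export
denoiser_config <- function(latent_hw = 8L, latent_c = 4L, width = 32L,
                            d_t = 32L, d_tau = 32L, d_k = 32L, m_tokens = 4L,
                            embed_dim = 512L) {
  abort_if(embed_dim %% m_tokens != 0, "m_tokens must divide embed_dim")
  structure(list(latent_hw = as.integer(latent_hw), latent_c = as.integer(latent_c),
                 width = as.integer(width), width2 = 2L * as.integer(width),
                 d_t = as.integer(d_t), d_tau = as.integer(d_tau),
                 d_k = as.integer(d_k), m_tokens = as.integer(m_tokens),
                 embed_dim = as.integer(embed_dim),
                 token_in = as.integer(embed_dim / m_tokens)),
            class = "denoiser_config")
}

denoiser_params <- function(cfg) {
  C <- cfg$width; C2 <- cfg$width2
  list(
    tau_w = he_init(c(cfg$token_in, cfg$d_tau), cfg$token_in),
    tau_b = rep(0, cfg$d_tau),
    sig_w = he_init(c(cfg$m_tokens * cfg$d_tau, cfg$d_t), cfg$m_tokens * cfg$d_tau),
    sig_b = rep(0, cfg$d_t),
    temb1_w = he_init(c(cfg$d_t, 64), cfg$d_t), temb1_b = rep(0, 64),
    temb2_w = he_init(c(64, C2), 64), temb2_b = rep(0, C2),
    in_w = he_init(c(3, 3, cfg$latent_c, C), 9 * cfg$latent_c), in_b = rep(0, C),
    down_w = he_init(c(3, 3, C, C2), 9 * C), down_b = rep(0, C2),
    attn_wq = he_init(c(C2, cfg$d_k), C2),
    attn_wk = he_init(c(cfg$d_tau, cfg$d_k), cfg$d_tau),
    attn_wv = he_init(c(cfg$d_tau, cfg$d_k), cfg$d_tau),
    attn_wo = he_init(c(cfg$d_k, C2), cfg$d_k) * 0.1,
    mid_w = he_init(c(3, 3, C2, C2), 9 * C2), mid_b = rep(0, C2),
    up_w = he_init(c(3, 3, C + C2, C), 9 * (C + C2)), up_b = rep(0, C),
    out_w = he_init(c(3, 3, C, cfg$latent_c), 9 * C) * 0.1,
    out_b = rep(0, cfg$latent_c)
  )
}

# parameter groups updated during fine-tuning (besides the EEG encoder)
finetune_groups <- function() {
  c("attn_wq", "attn_wk", "attn_wv", "attn_wo", "tau_w", "tau_b",
    "sig_w", "sig_b")
}

# tau projector: y (b, embed_dim) -> tokens (b, M, d_tau)
tau_fwd <- function(p, cfg, y) {
  b <- nrow(y)
  ym <- y
  dim(ym) <- NULL
  tok_in <- array(ym, dim = c(b, cfg$token_in, cfg$m_tokens))  # split embedding
  tok_mat <- aperm(tok_in, c(1, 3, 2))                         # (b, M, token_in)
  dim(tok_mat) <- c(b * cfg$m_tokens, cfg$token_in)
  tk <- dense_fwd(tok_mat, p$tau_w, p$tau_b)
  tokens <- tk$out
  dim(tokens) <- c(b, cfg$m_tokens, cfg$d_tau)
  list(out = tokens, cache = list(tok_mat = tok_mat, b = b))
}

tau_bwd <- function(p, cfg, dtokens, cache) {
  b <- cache$b
  dm <- dtokens
  dim(dm) <- c(b * cfg$m_tokens, cfg$d_tau)
  d <- dense_bwd(dm, p$tau_w, cache$tok_mat)
  dtok <- d$dx
  dim(dtok) <- c(b, cfg$m_tokens, cfg$token_in)
  dy <- aperm(dtok, c(1, 3, 2))
  dim(dy) <- c(b, cfg$embed_dim)
  list(dy = dy, dtau_w = d$dW, dtau_b = d$db)
}

# full denoiser forward: z (b,h,h,c), t int vector, tokens (b,M,d_tau)
unet_fwd <- function(p, cfg, z, t, tokens, double_cond = TRUE) {
  b <- dim(z)[1]
  cache <- list()
  te <- time_embedding(t, cfg$d_t)
  if (double_cond) {
    tokf <- tokens; dim(tokf) <- c(b, cfg$m_tokens * cfg$d_tau)
    sg <- dense_fwd(tokf, p$sig_w, p$sig_b)
    te <- te + sg$out
    cache$sig <- sg$cache
  }
  cache$double_cond <- double_cond
  t1 <- dense_fwd(te, p$temb1_w, p$temb1_b)
  a1 <- silu_fwd(t1$out)
  t2 <- dense_fwd(a1$out, p$temb2_w, p$temb2_b)       # (b, C2)
  cache$t1 <- t1$cache; cache$a1 <- a1$cache; cache$t2 <- t2$cache
  cin <- conv2d_fwd(z, p$in_w, p$in_b, stride = 1L, pad = 1L)
  h0a <- elu_fwd(cin$out)                              # (b, h, h, C)
  cache$cin <- cin$cache; cache$h0a <- h0a$cache
  dn <- conv2d_fwd(h0a$out, p$down_w, p$down_b, stride = 2L, pad = 1L)
  h1 <- dn$out                                         # (b, h/2, h/2, C2)
  d1 <- dim(h1)
  # add time embedding per channel
  for (cc in seq_len(d1[4])) h1[, , , cc] <- h1[, , , cc] + t2$out[, cc]
  h1a <- elu_fwd(h1)
  cache$dn <- dn$cache; cache$h1a <- h1a$cache; cache$d1 <- d1
  # cross-attention over spatial positions, per batch item
  nq <- d1[2] * d1[3]
  hattn <- h1a$out
  cache$attn <- vector("list", b)
  for (i in seq_len(b)) {
    phi <- h1a$out[i, , , ]
    dim(phi) <- c(nq, d1[4])
    af <- attn_fwd(phi, tokens[i, , ], p$attn_wq, p$attn_wk, p$attn_wv, p$attn_wo)
    upd <- phi + af$out                                # residual
    dim(upd) <- c(d1[2], d1[3], d1[4])
    hattn[i, , , ] <- upd
    cache$attn[[i]] <- af$cache
  }
  md <- conv2d_fwd(hattn, p$mid_w, p$mid_b, stride = 1L, pad = 1L)
  h2 <- elu_fwd(md$out)
  cache$md <- md$cache; cache$h2 <- h2$cache
  us <- upsample2_fwd(h2$out)                          # (b, h, h, C2)
  cache$us <- us$cache
  catd <- c(dim(us$out)[1:3], dim(us$out)[4] + dim(h0a$out)[4])
  hc <- array(0, dim = catd)
  hc[, , , seq_len(dim(us$out)[4])] <- us$out
  hc[, , , dim(us$out)[4] + seq_len(dim(h0a$out)[4])] <- h0a$out
  cache$c2w <- dim(us$out)[4]
  up <- conv2d_fwd(hc, p$up_w, p$up_b, stride = 1L, pad = 1L)
  h3 <- elu_fwd(up$out)
  cache$up <- up$cache; cache$h3 <- h3$cache
  fo <- conv2d_fwd(h3$out, p$out_w, p$out_b, stride = 1L, pad = 1L)
  cache$fo <- fo$cache
  list(out = fo$out, cache = cache)
}

unet_bwd <- function(p, cfg, dout, cache) {
  g <- list()
  b <- dim(dout)[1]
  bo <- conv2d_bwd(dout, p$out_w, cache$fo); g$out_w <- bo$dW; g$out_b <- bo$db
  dx <- elu_bwd(bo$dx, cache$h3)
  bu <- conv2d_bwd(dx, p$up_w, cache$up); g$up_w <- bu$dW; g$up_b <- bu$db
  c2w <- cache$c2w
  dus <- bu$dx[, , , seq_len(c2w), drop = FALSE]
  dh0_skip <- bu$dx[, , , c2w + seq_len(dim(bu$dx)[4] - c2w), drop = FALSE]
  dh2 <- upsample2_bwd(dus, cache$us)
  dh2 <- elu_bwd(dh2, cache$h2)
  bm <- conv2d_bwd(dh2, p$mid_w, cache$md); g$mid_w <- bm$dW; g$mid_b <- bm$db
  d1 <- cache$d1
  nq <- d1[2] * d1[3]
  dh1a <- bm$dx
  dtokens <- array(0, dim = c(b, cfg$m_tokens, cfg$d_tau))
  g$attn_wq <- 0 * p$attn_wq; g$attn_wk <- 0 * p$attn_wk
  g$attn_wv <- 0 * p$attn_wv; g$attn_wo <- 0 * p$attn_wo
  for (i in seq_len(b)) {
    dupd <- dh1a[i, , , ]
    dim(dupd) <- c(nq, d1[4])
    ab <- attn_bwd(dupd, p$attn_wq, p$attn_wk, p$attn_wv, p$attn_wo, cache$attn[[i]])
    dphi <- dupd + ab$dphi                             # residual
    dim(dphi) <- c(d1[2], d1[3], d1[4])
    dh1a[i, , , ] <- dphi
    dtokens[i, , ] <- ab$dctx
    g$attn_wq <- g$attn_wq + ab$dwq; g$attn_wk <- g$attn_wk + ab$dwk
    g$attn_wv <- g$attn_wv + ab$dwv; g$attn_wo <- g$attn_wo + ab$dwo
  }
  dh1 <- elu_bwd(dh1a, cache$h1a)
  # time-embedding pathway
  dt2 <- matrix(0, b, d1[4])
  for (cc in seq_len(d1[4])) {
    sl <- dh1[, , , cc]
    dim(sl) <- c(b, d1[2] * d1[3])
    dt2[, cc] <- rowSums(sl)
  }
  bt2 <- dense_bwd(dt2, p$temb2_w, cache$t2); g$temb2_w <- bt2$dW; g$temb2_b <- bt2$db
  dte <- silu_bwd(bt2$dx, cache$a1)
  bt1 <- dense_bwd(dte, p$temb1_w, cache$t1); g$temb1_w <- bt1$dW; g$temb1_b <- bt1$db
  if (cache$double_cond) {
    bs <- dense_bwd(bt1$dx, p$sig_w, cache$sig)
    g$sig_w <- bs$dW; g$sig_b <- bs$db
    dtokf <- bs$dx
    dim(dtokf) <- c(b, cfg$m_tokens, cfg$d_tau)
    dtokens <- dtokens + dtokf
  }
  bd <- conv2d_bwd(dh1, p$down_w, cache$dn); g$down_w <- bd$dW; g$down_b <- bd$db
  dh0 <- bd$dx + dh0_skip
  dh0 <- elu_bwd(dh0, cache$h0a)
  bi <- conv2d_bwd(dh0, p$in_w, cache$cin); g$in_w <- bi$dW; g$in_b <- bi$db
  list(dz = bi$dx, dtokens = dtokens, grads = g)
}

#' Noise-prediction training loss of the conditioned latent diffusion model
#'
#' Draws a uniform time step and standard-normal noise per latent, forms
#' the noised latent `z_t = sqrt(alpha_bar_t) z + sqrt(1 - alpha_bar_t) eps`
#' and returns the mean squared error between the injected and predicted
#' noise. With `double_cond = TRUE` the conditioning enters both through
#' cross-attention tokens and through the time-step embedding; with
#' `FALSE` only the cross-attention pathway is active.
#'
#' @param z `(b, h, h, c)` clean latents.
#' @param y `(b, embed_dim)` conditioning embeddings.
#' @param p denoiser parameter list.
#' @param cfg a [denoiser_config()].
#' @param schedule a [diffusion_schedule()].
#' @param double_cond toggle the time-step conditioning pathway.
#' @param grads also compute parameter gradients.
#' @param model optional override of the denoiser function (testing hook):
#'   `function(zt, t, tokens) -> eps_hat`.
#' @return list with `loss`, and when requested `grads` plus `dy` (gradient
#'   on the conditioning embeddings).
#' @export
diffusion_loss <- function(z, y, p, cfg, schedule, double_cond = TRUE,
                           grads = FALSE, model = NULL) {
  b <- dim(z)[1]
  abort_if(ncol(y) != cfg$embed_dim, "embedding width mismatch")
  t <- sample.int(schedule$T_steps, b, replace = TRUE)
  eps <- array(stats::rnorm(length(z)), dim = dim(z))
  ab <- schedule$alpha_bar[t]
  zt <- z; epshat <- NULL
  for (i in seq_len(b)) {
    zt[i, , , ] <- sqrt(ab[i]) * z[i, , , ] + sqrt(1 - ab[i]) * eps[i, , , ]
  }
  if (!is.null(model)) {
    pred <- model(zt, t, y)
    return(list(loss = mean((eps - pred)^2)))
  }
  tau <- tau_fwd(p, cfg, y)
  fw <- unet_fwd(p, cfg, zt, t, tau$out, double_cond)
  diff <- fw$out - eps
  loss <- mean(diff^2)
  if (!grads) return(list(loss = loss))
  bw <- unet_bwd(p, cfg, 2 * diff / length(diff), fw$cache)
  tb <- tau_bwd(p, cfg, bw$dtokens, tau$cache)
  g <- bw$grads
  g$tau_w <- tb$dtau_w; g$tau_b <- tb$dtau_b
  list(loss = loss, grads = g, dy = tb$dy)
}

#' Pretrain the toy latent diffusion model
#'
#' Trains the full denoiser (plus both projectors) on image latents,
#' conditioned on fixed per-class anchor embeddings -- the stand-in for
#' the separate conditioning context the full-scale model is pretrained
#' in. Fine-tuning later swaps in EEG embeddings through the same
#' projectors.
#'
#' @param latents `(n, h, h, c)` scaled latents.
#' @param labels 0-based class label per latent.
#' @param cfg a [denoiser_config()].
#' @param schedule a [diffusion_schedule()].
#' @param steps optimizer steps.
#' @param batch_size,lr training settings.
#' @param double_cond train with both conditioning pathways.
#' @param seed run seed.
#' @return list: `params`, `anchors` (class x embed_dim matrix), `history`.
#' @export
train_ldm <- function(latents, labels, cfg, schedule, steps = 400L,
                      batch_size = 16L, lr = 2e-3, double_cond = TRUE,
                      seed = 1L) {
  n <- dim(latents)[1]
  k <- max(labels) + 1L
  with_seed(seed, {
    p <- denoiser_params(cfg)
    anchors <- matrix(stats::rnorm(k * cfg$embed_dim), k, cfg$embed_dim)
    anchors <- anchors / sqrt(rowSums(anchors^2)) * sqrt(cfg$embed_dim)
    state <- adamw_init(p)
    hist <- numeric(steps)
    for (s in seq_len(steps)) {
      idx <- sample.int(n, batch_size, replace = batch_size > n)
      res <- diffusion_loss(latents[idx, , , , drop = FALSE],
                            anchors[labels[idx] + 1L, , drop = FALSE],
                            p, cfg, schedule, double_cond, grads = TRUE)
      # cosine decay to 10% of the peak LR stabilizes the un-normalized net
      lr_s <- lr * (0.55 + 0.45 * cos(pi * (s - 1) / steps))
      upd <- adamw_step(p, res$grads, state, lr_s, weight_decay = 1e-6,
                        decay_mask = decay_params(p))
      p <- upd$params; state <- upd$state
      hist[s] <- res$loss
    }
    list(params = p, anchors = anchors, history = hist)
  })
}

#' PLMS sampling from the conditioned denoiser
#'
#' Deterministic pseudo linear multi-step sampler: noise predictions are
#' buffered and combined with Adams-Bashforth coefficients (orders 1-4,
#' warming up until four evaluations are available); each update moves the
#' latent along the DDIM transfer using the combined prediction.
#'
#' @param p denoiser parameters.
#' @param cfg a [denoiser_config()].
#' @param schedule a [diffusion_schedule()].
#' @param y single conditioning embedding (length `embed_dim`).
#' @param steps number of sampling steps (<= `T_steps`).
#' @param seed seed for the initial latent.
#' @param double_cond use the time-step conditioning pathway.
#' @param model optional denoiser override `function(zt, t, y) -> eps_hat`
#'   (testing hook).
#' @return the final latent `(h, h, c)` array.
#' @export
sample_plms <- function(p, cfg, schedule, y, steps = 25L, seed = 1L,
                        double_cond = TRUE, model = NULL) {
  abort_if(steps < 1 || steps > schedule$T_steps, "steps must be in [1, T]")
  hw <- cfg$latent_hw
  x <- with_seed(seed, array(stats::rnorm(hw * hw * cfg$latent_c),
                             dim = c(1, hw, hw, cfg$latent_c)))
  ts <- unique(round(seq(schedule$T_steps, 1, length.out = steps)))
  ab_of <- function(t) if (t <= 0) 1 else schedule$alpha_bar[t]
  ym <- matrix(y, nrow = 1)
  tokens <- if (is.null(model)) tau_fwd(p, cfg, ym)$out else NULL
  buf <- list()
  for (i in seq_along(ts)) {
    t <- ts[i]
    t_next <- if (i < length(ts)) ts[i + 1] else 0L
    e_t <- if (is.null(model)) {
      unet_fwd(p, cfg, x, t, tokens, double_cond)$out
    } else {
      model(x, t, ym)
    }
    buf <- c(buf, list(e_t))
    nb <- length(buf)
    e_prime <- if (nb == 1) {
      buf[[1]]
    } else if (nb == 2) {
      (3 * buf[[2]] - buf[[1]]) / 2
    } else if (nb == 3) {
      (23 * buf[[3]] - 16 * buf[[2]] + 5 * buf[[1]]) / 12
    } else {
      (55 * buf[[nb]] - 59 * buf[[nb - 1]] + 37 * buf[[nb - 2]] - 9 * buf[[nb - 3]]) / 24
    }
    if (nb > 4) buf <- buf[-1]
    ab_t <- ab_of(t); ab_n <- ab_of(t_next)
    x0 <- (x - sqrt(1 - ab_t) * e_prime) / sqrt(ab_t)
    x <- sqrt(ab_n) * x0 + sqrt(1 - ab_n) * e_prime
  }
  out <- x[1, , , ]
  dim(out) <- c(hw, hw, cfg$latent_c)
  out
}
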