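# Minimal neural-network core on BLAS matrix ops: layer primitives with
# hand-written backward passes, AdamW, and the one-cycle schedule.
# EEG-side activations use a channel-last (batch, time, feature) layout so
# that batch-norm, pointwise convolutions and flattening are reshape-only.

`%||%` <- function(a, b) if (is.null(a)) b else a

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

## ---- temporal convolution (shared filter bank over EEG channels) ----

# x: (batch, C, T); W: (F1, K); same padding along T
# returns (batch, C, T, F1)
conv_temporal_fwd <- function(x, W) {
  d <- dim(x); batch <- d[1]; C <- d[2]; Tn <- d[3]; K <- ncol(W)
  pl <- (K - 1L) %/% 2L
  xp <- array(0, dim = c(batch, C, Tn + K - 1L))
  xp[, , pl + seq_len(Tn)] <- x
  M <- xp; dim(M) <- c(batch * C, Tn + K - 1L)
  cols <- as.vector(outer(seq_len(Tn), 0:(K - 1L), "+"))
  A <- M[, cols]; dim(A) <- c(batch * C * Tn, K)
  Y <- A %*% t(W)
  dim(Y) <- c(batch, C, Tn, nrow(W))
  list(out = Y, cache = list(A = A, dims = d, K = K, pl = pl))
}

conv_temporal_bwd <- function(dout, W, cache) {
  d <- cache$dims; batch <- d[1]; C <- d[2]; Tn <- d[3]; K <- cache$K
  dY <- dout; dim(dY) <- c(batch * C * Tn, nrow(W))
  dW <- t(crossprod(cache$A, dY))
  dA <- dY %*% W
  dim(dA) <- c(batch * C, Tn, K)
  dMp <- matrix(0, batch * C, Tn + K - 1L)
  for (k in seq_len(K)) dMp[, k + 0:(Tn - 1L)] <- dMp[, k + 0:(Tn - 1L)] + dA[, , k]
  dx <- dMp[, cache$pl + seq_len(Tn), drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = dW)
}

## ---- depthwise spatial convolution over the full channel extent -----

# h: (batch, C, T, F1); W: (F1, D, C) -> out (batch, T, F1*D)
depthwise_spatial_fwd <- function(h, W) {
  d <- dim(h); batch <- d[1]; C <- d[2]; Tn <- d[3]; F1 <- d[4]; D <- dim(W)[2]
  out <- array(0, dim = c(batch, Tn, F1 * D))
  mats <- vector("list", F1)
  for (f in seq_len(F1)) {
    hf <- h[, , , f]
    dim(hf) <- c(batch, C, Tn)
    hf <- aperm(hf, c(1, 3, 2))
    dim(hf) <- c(batch * Tn, C)
    wf <- W[f, , ]; dim(wf) <- c(D, C)
    yf <- tcrossprod(hf, wf)                  # (batch*T, D)
    dim(yf) <- c(batch, Tn, D)
    out[, , (f - 1L) * D + seq_len(D)] <- yf
    mats[[f]] <- hf
  }
  list(out = out, cache = list(mats = mats, dims = d, D = D))
}

depthwise_spatial_bwd <- function(dout, W, cache) {
  d <- cache$dims; batch <- d[1]; C <- d[2]; Tn <- d[3]; F1 <- d[4]; D <- cache$D
  dW <- array(0, dim = dim(W))
  dh <- array(0, dim = d)
  for (f in seq_len(F1)) {
    df <- dout[, , (f - 1L) * D + seq_len(D)]
    dim(df) <- c(batch * Tn, D)
    dW[f, , ] <- crossprod(df, cache$mats[[f]])
    wf <- W[f, , ]; dim(wf) <- c(D, C)
    dhf <- df %*% wf                          # (batch*T, C)
    dim(dhf) <- c(batch, Tn, C)
    dh[, , , f] <- aperm(dhf, c(1, 3, 2))
  }
  list(dx = dh, dW = dW)
}

## ---- batch normalization over the last (feature) dimension ----------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x); Fc <- d[length(d)]; nb <- prod(d) / Fc
  m <- x; dim(m) <- c(nb, Fc)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  a <- gamma * inv
  b2 <- beta - mu * a
  y <- m
  for (f in seq_len(Fc)) y[, f] <- y[, f] * a[f] + b2[f]
  dim(y) <- d
  list(out = y, run_mean = run_mean, run_var = run_var,
       cache = list(m = m, mu = mu, inv = inv, training = training, d = d))
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$d; Fc <- d[length(d)]; nb <- prod(d) / Fc
  dx <- dy; dim(dx) <- c(nb, Fc)
  dg <- numeric(Fc); db <- numeric(Fc)
  for (f in seq_len(Fc)) {
    dmf <- dx[, f]
    xf <- (cache$m[, f] - cache$mu[f]) * cache$inv[f]
    dg[f] <- sum(dmf * xf)
    db[f] <- sum(dmf)
    dx[, f] <- if (cache$training) {
      gamma[f] * cache$inv[f] * (dmf - db[f] / nb - xf * dg[f] / nb)
    } else {
      dmf * gamma[f] * cache$inv[f]
    }
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dg, dbeta = db)
}

## ---- activations ----------------------------------------------------

elu_fwd <- function(x, alpha = 1) {
  neg <- x <= 0
  y <- x
  y[neg] <- alpha * (exp(x[neg]) - 1)
  list(out = y, cache = list(y = y, alpha = alpha, neg = neg))
}

elu_bwd <- function(dy, cache) {
  dx <- dy
  dx[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + cache$alpha)
  dx
}

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, cache = list(x = x, s = s))
}

silu_bwd <- function(dy, cache) {
  dy * (cache$s * (1 + cache$x * (1 - cache$s)))
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = y)
}

sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

## ---- pooling along the middle (time) dimension of (b, T, F) ---------

pool_time_fwd <- function(x, p, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  d <- dim(x); To <- d[2] %/% p
  xr <- x[, seq_len(To * p), , drop = FALSE]
  dim(xr) <- c(d[1], p, To, d[3])
  if (mode == "mean") {
    out <- array(0, dim = c(d[1], To, d[3]))
    for (i in seq_len(p)) out <- out + xr[, i, , ]
    dim(out) <- c(d[1], To, d[3])
    return(list(out = out / p, cache = list(d = d, p = p, To = To, mode = mode)))
  }
  out <- xr[, 1, , , drop = FALSE]; dim(out) <- c(d[1], To, d[3])
  idx <- array(1L, dim = c(d[1], To, d[3]))
  for (i in seq_len(p)[-1]) {
    sl <- xr[, i, , , drop = FALSE]; dim(sl) <- c(d[1], To, d[3])
    upd <- sl > out
    out[upd] <- sl[upd]
    idx[upd] <- i
  }
  list(out = out, cache = list(d = d, p = p, To = To, idx = idx, mode = mode))
}

pool_time_bwd <- function(dy, cache) {
  d <- cache$d; p <- cache$p; To <- cache$To
  dxr <- array(0, dim = c(d[1], p, To, d[3]))
  if (cache$mode == "mean") {
    for (i in seq_len(p)) dxr[, i, , ] <- dy / p
  } else {
    z <- array(0, dim = dim(dy))
    for (i in seq_len(p)) {
      sl <- z
      m <- cache$idx == i
      sl[m] <- dy[m]
      dxr[, i, , ] <- sl
    }
  }
  dim(dxr) <- c(d[1], p * To, d[3])
  dx <- array(0, dim = d)
  dx[, seq_len(p * To), ] <- dxr
  dx
}

## ---- dropout --------------------------------------------------------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= p, dim = dim(x)) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## ---- depthwise temporal + pointwise (separable) convolution ---------

# x: (batch, T, C); W: (C, K); same padding along T
depthwise_temporal_fwd <- function(x, W) {
  d <- dim(x); K <- ncol(W)
  pl <- (K - 1L) %/% 2L
  xp <- array(0, dim = c(d[1], d[2] + K - 1L, d[3]))
  xp[, pl + seq_len(d[2]), ] <- x
  out <- array(0, dim = d)
  for (k in seq_len(K)) {
    sl <- xp[, k + 0:(d[2] - 1L), , drop = FALSE]
    dim(sl) <- c(d[1] * d[2], d[3])
    o <- out; dim(o) <- c(d[1] * d[2], d[3])
    for (f in seq_len(d[3])) o[, f] <- o[, f] + sl[, f] * W[f, k]
    dim(o) <- d
    out <- o
  }
  list(out = out, cache = list(xp = xp, d = d, K = K, pl = pl))
}

depthwise_temporal_bwd <- function(dy, W, cache) {
  d <- cache$d; K <- cache$K
  dW <- matrix(0, d[3], K)
  dxp <- array(0, dim = dim(cache$xp))
  dym <- dy; dim(dym) <- c(d[1] * d[2], d[3])
  for (k in seq_len(K)) {
    sl_idx <- k + 0:(d[2] - 1L)
    sl <- cache$xp[, sl_idx, , drop = FALSE]
    dim(sl) <- c(d[1] * d[2], d[3])
    dW[, k] <- colSums(dym * sl)
    dslk <- dym
    for (f in seq_len(d[3])) dslk[, f] <- dym[, f] * W[f, k]
    dim(dslk) <- d
    dxp[, sl_idx, ] <- dxp[, sl_idx, ] + dslk
  }
  dx <- dxp[, cache$pl + seq_len(d[2]), , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dW = dW)
}

# x: (batch, T, Cin); W: (Cin, Cout)
pointwise_fwd <- function(x, W) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  y <- xm %*% W
  dim(y) <- c(d[1], d[2], ncol(W))
  list(out = y, cache = list(xm = xm, d = d))
}

pointwise_bwd <- function(dy, W, cache) {
  d <- cache$d
  dym <- dy; dim(dym) <- c(d[1] * d[2], ncol(W))
  dW <- crossprod(cache$xm, dym)
  dx <- tcrossprod(dym, W)
  dim(dx) <- d
  list(dx = dx, dW = dW)
}

## ---- dense / softmax ------------------------------------------------

dense_fwd <- function(x, W, b) {
  y <- x %*% W
  list(out = y + rep(b, each = nrow(y)), cache = x)
}

dense_bwd <- function(dy, W, cache) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache, dy), db = colSums(dy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels: 1-based integer class indices
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

## ---- optimizer and schedule -----------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

# decoupled weight decay; `decay_mask` names params that receive decay
adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       decay_mask = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    wd <- if (is.null(decay_mask) || nm %in% decay_mask) weight_decay else 0
    params[[nm]] <- params[[nm]] - lr * (upd + wd * params[[nm]])
  }
  list(params = params, state = state)
}

#' One-cycle learning-rate schedule
#'
#' Cosine warm-up from `max_lr / div_factor` to `max_lr` over the first
#' `pct_start` fraction of steps, then cosine annealing down to
#' `max_lr / final_div_factor`.
#'
#' @param step 1-based step index.
#' @param total_steps total number of optimizer steps.
#' @param max_lr peak learning rate.
#' @param pct_start warm-up fraction.
#' @param div_factor initial LR divisor.
#' @param final_div_factor final LR divisor.
#' @return the learning rate at `step`.
#' @export
one_cycle_lr <- function(step, total_steps, max_lr, pct_start = 0.3,
                         div_factor = 25, final_div_factor = 1e4) {
  warm <- max(1, round(total_steps * pct_start))
  if (step <= warm) {
    lo <- max_lr / div_factor
    frac <- (step - 1) / max(1, warm - 1)
    lo + (max_lr - lo) * (1 - cos(pi * frac)) / 2
  } else {
    lo <- max_lr / final_div_factor
    frac <- (step - warm) / max(1, total_steps - warm)
    lo + (max_lr - lo) * (1 + cos(pi * frac)) / 2
  }
}
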