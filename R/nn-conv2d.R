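# 2-D convolution primitives for the image-side networks (latent
# autoencoder, conditioned denoiser, surrogate classifier). Image tensors
# are channel-last: (batch, H, W, C).

# W: (kh, kw, Cin, Cout); stride s; zero padding p
conv2d_fwd <- function(x, W, b = NULL, stride = 1L, pad = 1L) {
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- d[2]; Wd <- d[3]
  xp <- array(0, dim = c(d[1], H + 2 * pad, Wd + 2 * pad, cin))
  if (pad > 0) xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- x else xp <- x
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (Wd + 2 * pad - kw) %/% stride + 1L
  out <- matrix(0, d[1] * Ho * Wo, cout)
  for (i in seq_len(kh)) {
    hi <- i + stride * (0:(Ho - 1L))
    for (j in seq_len(kw)) {
      wi <- j + stride * (0:(Wo - 1L))
      xs <- xp[, hi, wi, , drop = FALSE]
      dim(xs) <- c(d[1] * Ho * Wo, cin)
      wk <- W[i, j, , ]; dim(wk) <- c(cin, cout)
      out <- out + xs %*% wk
    }
  }
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  dim(out) <- c(d[1], Ho, Wo, cout)
  list(out = out, cache = list(xp = xp, d = d, stride = stride, pad = pad,
                               Ho = Ho, Wo = Wo))
}

conv2d_bwd <- function(dout, W, cache) {
  d <- cache$d; s <- cache$stride; pad <- cache$pad
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  dm <- dout; dim(dm) <- c(d[1] * Ho * Wo, cout)
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(cache$xp))
  for (i in seq_len(kh)) {
    hi <- i + s * (0:(Ho - 1L))
    for (j in seq_len(kw)) {
      wi <- j + s * (0:(Wo - 1L))
      xs <- cache$xp[, hi, wi, , drop = FALSE]
      dim(xs) <- c(d[1] * Ho * Wo, cin)
      dW[i, j, , ] <- crossprod(xs, dm)
      wk <- W[i, j, , ]; dim(wk) <- c(cin, cout)
      dxs <- tcrossprod(dm, wk)
      dim(dxs) <- c(d[1], Ho, Wo, cin)
      dxp[, hi, wi, ] <- dxp[, hi, wi, ] + dxs
    }
  }
  dx <- if (pad > 0) dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, dW = dW, db = colSums(dm))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  out <- x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , drop = FALSE]
  list(out = out, cache = d)
}

upsample2_bwd <- function(dy, d) {
  i1 <- seq(1, 2 * d[2], by = 2); i2 <- i1 + 1
  j1 <- seq(1, 2 * d[3], by = 2); j2 <- j1 + 1
  dx <- dy[, i1, j1, , drop = FALSE] + dy[, i1, j2, , drop = FALSE] +
    dy[, i2, j1, , drop = FALSE] + dy[, i2, j2, , drop = FALSE]
  dim(dx) <- d
  dx
}

# global average pool over H, W: (b, H, W, C) -> (b, C)
gap_fwd <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- apply(m, c(1, 3), mean)
  dim(out) <- c(d[1], d[4])
  list(out = out, cache = d)
}

gap_bwd <- function(dy, d) {
  n <- d[2] * d[3]
  dx <- array(0, dim = d)
  for (c4 in seq_len(d[4])) dx[, , , c4] <- dy[, c4] / n
  dx
}
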