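# Low-level neural network layers with hand-derived backpropagation.
# Layout conventions:
#   feature maps   : arrays [H (time), W (mel), C (channels)]
#   conv weights   : matrix [(kk*kk*Cin) x Cout], rows ordered offset-major
#                    (kernel row fastest, then kernel column), channel within
#                    offset; cross-correlation with zero ("same") padding
#   sequences      : matrices [T x D]
# All gradients are exact; see the finite-difference checks in the tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

im2col <- function(x, kk) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pad <- (kk - 1L) %/% 2L
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  cols <- matrix(0, H * W, kk * kk * C)
  o <- 0L
  for (dc in 0:(kk - 1L)) {
    for (dr in 0:(kk - 1L)) {
      blk <- xp[dr + seq_len(H), dc + seq_len(W), , drop = FALSE]
      cols[, o * C + seq_len(C)] <- matrix(blk, H * W, C)
      o <- o + 1L
    }
  }
  cols
}

col2im <- function(dcols, dims, kk) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]
  pad <- (kk - 1L) %/% 2L
  dxp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  o <- 0L
  for (dc in 0:(kk - 1L)) {
    for (dr in 0:(kk - 1L)) {
      dxp[dr + seq_len(H), dc + seq_len(W), ] <-
        dxp[dr + seq_len(H), dc + seq_len(W), ] +
        array(dcols[, o * C + seq_len(C)], c(H, W, C))
      o <- o + 1L
    }
  }
  dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

conv_forward <- function(x, W, b, kk = 3L) {
  d <- dim(x)
  cols <- im2col(x, kk)
  y <- cols %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = array(y, c(d[1], d[2], length(b))), cols = cols, in_dims = d)
}

conv_backward <- function(dy, cache, W, kk = 3L) {
  d <- dim(dy)
  dy_m <- matrix(dy, d[1] * d[2], d[3])
  list(
    dx = col2im(dy_m %*% t(W), cache$in_dims, kk),
    dW = crossprod(cache$cols, dy_m),
    db = colSums(dy_m)
  )
}

pool_indices <- function(H, W, C) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ri <- rep(seq(1L, by = 2L, length.out = Ho), times = Wo * C)
  ci <- rep(rep(seq(1L, by = 2L, length.out = Wo), each = Ho), times = C)
  chi <- rep(seq_len(C), each = Ho * Wo)
  base <- ri + (ci - 1L) * H + (chi - 1L) * H * W
  cbind(base, base + 1L, base + H, base + H + 1L)   # (+0,+0) (+1,0) (0,+1) (+1,+1)
}

maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  if (Ho < 1L || Wo < 1L) {
    abort(sprintf("feature map %dx%d too small for 2x2 pooling", H, W))
  }
  idx <- pool_indices(H, W, C)
  vals <- matrix(x[idx], nrow(idx), 4L)
  arg <- max.col(vals, ties.method = "first")
  sel <- idx[cbind(seq_len(nrow(idx)), arg)]
  list(y = array(x[sel], c(Ho, Wo, C)), sel = sel, in_dims = d)
}

maxpool_backward <- function(dy, cache) {
  dx <- array(0, cache$in_dims)
  dx[cache$sel] <- as.vector(dy)
  dx
}

relu <- function(x) pmax(x, 0)

# One residual convolution stage:
#   a1 = relu(conv1(x)); a2 = relu(conv2(a1)); a3 = conv3(a2)
#   stage output = maxpool(a1 + a3)
# With conv2/conv3 zeroed the stage reduces exactly to maxpool(a1): the skip
# path guards the first convolution's output against loss of information.
stage_forward <- function(x, w, kk) {
  c1 <- conv_forward(x, w$W1, w$b1, kk); a1 <- relu(c1$y)
  c2 <- conv_forward(a1, w$W2, w$b2, kk); a2 <- relu(c2$y)
  c3 <- conv_forward(a2, w$W3, w$b3, kk)
  pl <- maxpool_forward(a1 + c3$y)
  list(y = pl$y, c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, pl = pl)
}

stage_backward <- function(dy, cache, w, kk) {
  ds <- maxpool_backward(dy, cache$pl)
  b3 <- conv_backward(ds, cache$c3, w$W3, kk)
  da2 <- b3$dx * (cache$c2$y > 0)
  b2 <- conv_backward(da2, cache$c2, w$W2, kk)
  da1 <- (ds + b2$dx) * (cache$c1$y > 0)
  b1 <- conv_backward(da1, cache$c1, w$W1, kk)
  list(dx = b1$dx,
       dW1 = b1$dW, db1 = b1$db, dW2 = b2$dW, db2 = b2$db,
       dW3 = b3$dW, db3 = b3$db)
}

# LSTM, one direction. X: T x D. Weights Wx: D x 4H, Wh: H x 4H, b: 4H.
# Gate column blocks in order [input | forget | cell | output].
lstm_forward <- function(X, Wx, Wh, b) {
  Tn <- nrow(X); Hn <- nrow(Wh)
  XW <- X %*% Wx
  Hs <- matrix(0, Tn, Hn); Cs <- matrix(0, Tn, Hn)
  gates <- vector("list", Tn)
  h <- numeric(Hn); cc <- numeric(Hn)
  ii <- seq_len(Hn); fi <- Hn + ii; gi <- 2L * Hn + ii; oi <- 3L * Hn + ii
  for (t in seq_len(Tn)) {
    z <- XW[t, ] + as.numeric(h %*% Wh) + b
    i_g <- sigmoid(z[ii]); f_g <- sigmoid(z[fi])
    g_g <- tanh(z[gi]); o_g <- sigmoid(z[oi])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h <- o_g * tc
    Hs[t, ] <- h; Cs[t, ] <- cc
    gates[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g, tc = tc,
                       c_prev = c_prev)
  }
  list(H = Hs, gates = gates, X = X)
}

lstm_backward <- function(dH, cache, Wx, Wh) {
  X <- cache$X; Tn <- nrow(X); Hn <- ncol(dH)
  dXW <- matrix(0, Tn, 4L * Hn)
  dWh <- matrix(0, Hn, 4L * Hn); db <- numeric(4L * Hn)
  dh_next <- numeric(Hn); dc_next <- numeric(Hn)
  for (t in rev(seq_len(Tn))) {
    g <- cache$gates[[t]]
    dh <- dH[t, ] + dh_next
    do_g <- dh * g$tc
    dc <- dh * g$o * (1 - g$tc^2) + dc_next
    di <- dc * g$g; df <- dc * g$c_prev; dg <- dc * g$i
    dc_next <- dc * g$f
    dz <- c(di * g$i * (1 - g$i),
            df * g$f * (1 - g$f),
            dg * (1 - g$g^2),
            do_g * g$o * (1 - g$o))
    dXW[t, ] <- dz
    h_prev <- if (t > 1L) cache$H[t - 1L, ] else numeric(Hn)
    dWh <- dWh + outer(h_prev, dz)
    db <- db + dz
    dh_next <- as.numeric(Wh %*% dz)
  }
  list(dX = dXW %*% t(Wx), dWx = crossprod(X, dXW), dWh = dWh, db = db)
}

bilstm_forward <- function(X, w) {
  fw <- lstm_forward(X, w$fw_Wx, w$fw_Wh, w$fw_b)
  Xr <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  bw <- lstm_forward(Xr, w$bw_Wx, w$bw_Wh, w$bw_b)
  Hb <- bw$H[rev(seq_len(nrow(X))), , drop = FALSE]
  list(H = cbind(fw$H, Hb), fw = fw, bw = bw)
}

bilstm_backward <- function(dH, cache, w) {
  Hn <- ncol(dH) %/% 2L
  Tn <- nrow(dH)
  gf <- lstm_backward(dH[, seq_len(Hn), drop = FALSE], cache$fw,
                      w$fw_Wx, w$fw_Wh)
  dHb_rev <- dH[rev(seq_len(Tn)), Hn + seq_len(Hn), drop = FALSE]
  gb <- lstm_backward(dHb_rev, cache$bw, w$bw_Wx, w$bw_Wh)
  dX <- gf$dX + gb$dX[rev(seq_len(Tn)), , drop = FALSE]
  list(dX = dX,
       fw_dWx = gf$dWx, fw_dWh = gf$dWh, fw_db = gf$db,
       bw_dWx = gb$dWx, bw_dWh = gb$dWh, bw_db = gb$db)
}

# Attention pooling. H: T x d_h. Wa: d_h x d_a, b: d_a, Wb: d_a.
# score_i = sigmoid(h_i Wa + b) . Wb ; alpha = softmax(score) ; r = sum alpha_i h_i
attn_forward <- function(H, Wa, b, Wb) {
  A <- sweep(H %*% Wa, 2, b, `+`)
  sg <- sigmoid(A)
  s <- as.numeric(sg %*% Wb)
  e <- exp(s - max(s))
  alpha <- e / sum(e)
  r <- as.numeric(crossprod(H, alpha))
  list(r = r, alpha = alpha, sg = sg, H = H)
}

attn_backward <- function(dr, cache, Wa, Wb) {
  H <- cache$H; alpha <- cache$alpha; sg <- cache$sg
  dH_r <- alpha %o% dr
  dalpha <- as.numeric(H %*% dr)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dWb <- as.numeric(crossprod(sg, ds))
  dsg <- ds %o% Wb
  dA <- dsg * sg * (1 - sg)
  list(dH = dH_r + dA %*% t(Wa),
       dWa = crossprod(H, dA), db = colSums(dA), dWb = dWb)
}

dense_forward <- function(r, w) {
  z1 <- as.numeric(w$W1 %*% r) + w$b1
  h1 <- relu(z1)
  logits <- as.numeric(w$W2 %*% h1) + w$b2
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  list(p = p, logits = logits, h1 = h1, z1 = z1, r = r)
}

dense_backward <- function(dlogits, cache, w) {
  dW2 <- dlogits %o% cache$h1
  db2 <- dlogits
  dh1 <- as.numeric(t(w$W2) %*% dlogits)
  dz1 <- dh1 * (cache$z1 > 0)
  list(dr = as.numeric(t(w$W1) %*% dz1),
       dW1 = dz1 %o% cache$r, db1 = dz1, dW2 = dW2, db2 = db2)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}
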