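test_that("convolution matches a literal cross-correlation loop", {
  set.seed(5)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  W <- matrix(rnorm(9 * 2 * 3), 9 * 2, 3)
  b <- rnorm(3)
  out <- courttone:::conv_forward(x, W, b, kk = 3L)$y
  # oracle: zero-padded cross-correlation, weight rows ordered kernel-row
  # fastest, then kernel column, channel within offset
  xp <- array(0, c(7, 7, 2))
  xp[2:6, 2:6, ] <- x
  ref <- array(0, c(5, 5, 3))
  for (o in 1:3) {
    for (r in 1:5) for (cc in 1:5) {
      acc <- b[o]
      for (dc in 0:2) for (dr in 0:2) for (ch in 1:2) {
        wrow <- (dc * 3 + dr) * 2 + ch
        acc <- acc + xp[r + dr, cc + dc, ch] * W[wrow, o]
      }
      ref[r, cc, o] <- acc
    }
  }
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("a 1x1 convolution is exactly a per-position channel mix", {
  set.seed(6)
  x <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  W <- matrix(rnorm(2 * 2), 2, 2)
  out <- courttone:::conv_forward(x, W, numeric(2), kk = 1L)$y
  ref <- array(0, c(4, 3, 2))
  for (o in 1:2) ref[, , o] <- x[, , 1] * W[1, o] + x[, , 2] * W[2, o]
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("zeroing the second and third convolutions leaves max-pool of the first", {
  cfg <- tiny_cfg()
  set.seed(2)
  x <- array(rnorm(12 * 8 * 3), c(12, 8, 3))
  w <- rescnn_init(cfg, 8)
  for (s in 1:2) {
    for (nm in c("_W2", "_b2", "_W3", "_b3")) {
      w[[paste0("s", s, nm)]] <- w[[paste0("s", s, nm)]] * 0
    }
  }
  got <- residual_conv_encode(x, w, cfg)
  h <- x
  for (s in 1:2) {
    a1 <- pmax(courttone:::conv_forward(
      h, w[[paste0("s", s, "_W1")]], w[[paste0("s", s, "_b1")]], 3L)$y, 0)
    h <- courttone:::maxpool_forward(a1)$y
  }
  expect_equal(got, matrix(h, dim(h)[1], dim(h)[2] * dim(h)[3]),
               tolerance = 1e-12)
})

test_that("pooling halves the time axis per stage and short inputs error", {
  cfg <- tiny_cfg()
  w <- rescnn_init(cfg, 8)
  x <- array(rnorm(13 * 8 * 3), c(13, 8, 3))
  expect_equal(nrow(residual_conv_encode(x, w, cfg)), 13 %/% 2 %/% 2)
  xs <- array(rnorm(3 * 8 * 3), c(3, 8, 3))
  expect_error(residual_conv_encode(xs, w, cfg), "at least 4")
})

test_that("a single LSTM cell reproduces the hand-evaluated gate equations", {
  # D = 2, H = 1; weights chosen by hand
  Wx <- matrix(c(0.1, -0.2, 0.3, 0.05, -0.1, 0.2, 0.4, -0.3), 2, 4)
  Wh <- matrix(c(0.5, -0.5, 0.25, 0.1), 1, 4)
  b <- c(0.01, 1, -0.02, 0.03)
  x <- c(0.7, -1.2)
  out <- courttone:::lstm_forward(matrix(x, 1, 2), Wx, Wh, b)
  sig <- function(z) 1 / (1 + exp(-z))
  z <- as.numeric(x %*% Wx) + b      # h0 = 0
  i_g <- sig(z[1]); f_g <- sig(z[2]); g_g <- tanh(z[3]); o_g <- sig(z[4])
  c1 <- i_g * g_g                    # c0 = 0
  h1 <- o_g * tanh(c1)
  expect_equal(as.numeric(out$H), h1, tolerance = 1e-12)
})

test_that("with tied direction weights, reversing the input swaps and reverses the output halves", {
  cfg <- tiny_cfg()
  w <- rescnn_init(cfg, 8)
  w$bw_Wx <- w$fw_Wx; w$bw_Wh <- w$fw_Wh; w$bw_b <- w$fw_b
  lw <- courttone:::lstm_weights(w)
  set.seed(9)
  X <- matrix(rnorm(6 * nrow(w$fw_Wx)), 6)
  H <- bilstm_encode(X, lw)
  Hr <- bilstm_encode(X[6:1, , drop = FALSE], lw)
  Hn <- ncol(H) / 2
  expect_equal(Hr[6:1, Hn + seq_len(Hn)], H[, seq_len(Hn)], tolerance = 1e-12)
  expect_equal(Hr[6:1, seq_len(Hn)], H[, Hn + seq_len(Hn)], tolerance = 1e-12)
  expect_equal(nrow(H), 6)
  expect_error(bilstm_encode(matrix(numeric(0), 0, 3), lw), "non-empty")
})

test_that("attention weights form a probability vector and T = 1 returns h_1", {
  set.seed(4)
  theta <- list(Wa = matrix(rnorm(8), 4, 2), b = rnorm(2), Wb = rnorm(2))
  for (i in 1:20) {
    H <- matrix(rnorm(5 * 4), 5, 4)
    out <- attention_pool(H, theta)
    expect_equal(sum(out$alpha), 1, tolerance = 1e-6)
    expect_true(all(out$alpha > 0))
    expect_equal(out$r, as.numeric(crossprod(H, out$alpha)), tolerance = 1e-12)
  }
  h1 <- matrix(rnorm(4), 1, 4)
  out1 <- attention_pool(h1, theta)
  expect_equal(out1$alpha, 1)
  expect_equal(out1$r, as.numeric(h1))
  expect_error(attention_pool(matrix(rnorm(6), 2, 3), theta), "dimensions")
})

test_that("attention equals a step-by-step scalar evaluation on a small case", {
  H <- matrix(c(0.5, -1, 2, 0.3, -0.7, 1.1), 3, 2)
  theta <- list(Wa = matrix(c(0.2, -0.4, 0.6, 0.1), 2, 2),
                b = c(0.05, -0.1), Wb = c(1.5, -0.8))
  sig <- function(z) 1 / (1 + exp(-z))
  s <- numeric(3)
  for (i in 1:3) {
    a <- sig(as.numeric(H[i, ] %*% theta$Wa) + theta$b)
    s[i] <- sum(a * theta$Wb)
  }
  alpha <- exp(s) / sum(exp(s))
  r <- colSums(alpha * H)
  out <- attention_pool(H, theta)
  expect_equal(out$alpha, alpha, tolerance = 1e-9)
  expect_equal(out$r, r, tolerance = 1e-9)
})

test_that("the dense head is symmetric at zero weights and matches closed-form softmax", {
  w0 <- list(dense_W1 = matrix(0, 5, 8), dense_b1 = numeric(5),
             dense_W2 = matrix(0, 3, 5), dense_b2 = numeric(3))
  p <- classify_emotion(rnorm(8), w0)
  expect_equal(unname(p), rep(1 / 3, 3))
  w1 <- w0
  w1$dense_b2 <- c(log(2), 0, 0)
  expect_equal(unname(classify_emotion(rnorm(8), w1)), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
  set.seed(8)
  wr <- list(dense_W1 = matrix(rnorm(40), 5, 8), dense_b1 = rnorm(5),
             dense_W2 = matrix(rnorm(15), 3, 5), dense_b2 = rnorm(3))
  pr <- classify_emotion(rnorm(8), wr)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_true(all(pr >= 0))
})

test_that("analytic gradients agree with finite differences through the whole network", {
  cfg <- tiny_cfg()
  set.seed(1)
  x <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
  w <- rescnn_init(cfg, 8)
  fwd <- courttone:::rescnn_forward(x, w, cfg, keep_cache = TRUE)
  g <- courttone:::rescnn_backward(2L, fwd, w, cfg)
  loss_at <- function(ww) -log(courttone:::rescnn_forward(x, ww, cfg)$p[2])
  eps <- 1e-6
  for (nm in names(w)) {
    ks <- sample(length(w[[nm]]), min(3, length(w[[nm]])))
    for (i in ks) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      an <- g[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("r lies in the convex hull of the hidden states", {
  set.seed(11)
  theta <- list(Wa = matrix(rnorm(6), 3, 2), b = rnorm(2), Wb = rnorm(2))
  H <- matrix(rnorm(7 * 3), 7, 3)
  out <- attention_pool(H, theta)
  expect_true(all(out$r >= apply(H, 2, min) - 1e-12))
  expect_true(all(out$r <= apply(H, 2, max) + 1e-12))
})

test_that("training reduces the loss and memorizes a single example", {
  cfg <- tiny_cfg(epochs = 8L, batch_size = 8L, learning_rate = 5e-3)
  set.seed(3)
  # 30 linearly separated examples: class mean shifts the static channel
  xs <- lapply(1:30, function(i) {
    cls <- (i - 1) %% 3
    array(rnorm(8 * 8 * 3, mean = cls * 2), c(8, 8, 3))
  })
  ys <- EMOTIONS[((1:30 - 1) %% 3) + 1]
  m <- train_rescnn(xs, ys, cfg)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
  # single-example memorization
  cfg1 <- tiny_cfg(epochs = 300L, batch_size = 1L, learning_rate = 5e-3,
                   patience = 300L)
  # all classes must be present: train on three copies, one per class, then
  # check the fit drives per-example loss essentially to zero
  x1 <- lapply(0:2, function(cl) array(rnorm(8 * 8 * 3, mean = cl), c(8, 8, 3)))
  m1 <- train_rescnn(x1, EMOTIONS, cfg1)
  expect_lt(tail(m1$log$loss, 1), 0.01)
})

test_that("training refuses data with a missing class, naming it", {
  cfg <- tiny_cfg()
  xs <- lapply(1:4, function(i) array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  expect_error(train_rescnn(xs, c("angry", "angry", "neutral", "neutral"), cfg),
               "fear")
})

test_that("training is reproducible and prediction is deterministic", {
  cfg <- tiny_cfg(epochs = 3L)
  set.seed(10)
  xs <- lapply(1:9, function(i) array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  ys <- rep(EMOTIONS, 3)
  m1 <- train_rescnn(xs, ys, cfg)
  m2 <- train_rescnn(xs, ys, cfg)
  expect_equal(m1$log$loss, m2$log$loss, tolerance = 1e-12)
  w <- synthesize_utterance("fear", "defendant", 0.5, court_params(), seed = 2)
  mod <- structure(list(weights = m1$weights, cfg = cfg,
                        frame_params = frame_params(n_mel = 8),
                        levels = EMOTIONS, n_mel = 8, log = m1$log),
                   class = "rescnn")
  p1 <- predict_utterance(w, mod)
  p2 <- predict_utterance(w, mod)
  expect_identical(p1, p2)
  expect_equal(sum(p1$posterior), 1, tolerance = 1e-6)
  expect_equal(p1$label, EMOTIONS[which.max(p1$posterior)])
})

test_that("tidy and glance expose the training log and model summary", {
  cfg <- tiny_cfg(epochs = 2L)
  set.seed(12)
  xs <- lapply(1:6, function(i) array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  m <- train_rescnn(xs, rep(EMOTIONS, 2), cfg)
  td <- generics::tidy(m)
  expect_named(td, c("epoch", "loss"))
  gl <- generics::glance(m)
  expect_equal(gl$epochs, nrow(td))
  expect_gt(gl$n_parameters, 0)
})
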