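#' Configuration of the residual CNN + BiLSTM + attention classifier
#'
#' The classifier stacks: `n_residual_stages` residual convolution stages
#' (each three 3x3 convolutions with a skip connection from the first to the
#' third, followed by 2x2 max pooling over time x mel), a bidirectional LSTM
#' over the pooled time axis, attention pooling of the BiLSTM states into a
#' single representation, and a two-level dense network with a softmax over
#' the three emotion classes, trained with cross-entropy.
#'
#' @param n_kernels Convolution kernels per layer (default 128).
#' @param kernel_size Square kernel side, odd (default 3).
#' @param n_residual_stages Number of residual conv + pool stages (default 2).
#' @param pool_size Pooling factor; only 2 is supported.
#' @param lstm_hidden Hidden units per LSTM direction (default 128).
#' @param d_a Attention projection width (default 64).
#' @param dense_sizes The two dense levels; the last entry is the 3 emotion
#'   classes (default `c(64, 3)`).
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param patience,min_delta Early stopping: stop when the epoch training
#'   loss has improved by less than `min_delta` for `patience` epochs.
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return A list of class `rescnn_config`.
#' @export
rescnn_config <- function(n_kernels = 128L, kernel_size = 3L,
                          n_residual_stages = 2L, pool_size = 2L,
                          lstm_hidden = 128L, d_a = 64L,
                          dense_sizes = c(64L, 3L),
                          learning_rate = 1e-3, batch_size = 16L,
                          epochs = 30L, patience = 4L, min_delta = 1e-3,
                          seed = 1L) {
  if (n_kernels < 1) abort("`n_kernels` must be >= 1")
  if (kernel_size %% 2 != 1 || kernel_size < 1) abort("`kernel_size` must be odd")
  if (pool_size != 2L) abort("only `pool_size = 2` is supported")
  if (length(dense_sizes) != 2 || dense_sizes[2] != 3) {
    abort("`dense_sizes` must be two levels ending in the 3 emotion classes")
  }
  if (any(c(n_residual_stages, lstm_hidden, d_a, batch_size, epochs) < 1)) {
    abort("all model size/optimizer counts must be positive")
  }
  structure(list(
    n_kernels = as.integer(n_kernels), kernel_size = as.integer(kernel_size),
    n_residual_stages = as.integer(n_residual_stages),
    pool_size = as.integer(pool_size),
    lstm_hidden = as.integer(lstm_hidden), d_a = as.integer(d_a),
    dense_sizes = as.integer(dense_sizes),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    min_delta = min_delta, seed = as.integer(seed)
  ), class = "rescnn_config")
}

pooled_width <- function(n_mel, n_stages) {
  w <- n_mel
  for (s in seq_len(n_stages)) w <- w %/% 2L
  w
}

#' Initialize classifier weights
#'
#' Glorot-uniform weight matrices and zero biases (LSTM forget-gate biases
#' start at 1). Deterministic given `cfg$seed` and `n_mel`.
#'
#' @param cfg A [rescnn_config()].
#' @param n_mel Mel-band count of the input feature tensor.
#' @return Flat named list of weight arrays.
#' @export
rescnn_init <- function(cfg, n_mel) {
  K <- cfg$n_kernels; kk <- cfg$kernel_size
  Wp <- pooled_width(n_mel, cfg$n_residual_stages)
  if (Wp < 1L) abort(sprintf("n_mel = %d collapses to zero after %d pooling stages",
                             n_mel, cfg$n_residual_stages))
  D <- K * Wp
  Hn <- cfg$lstm_hidden
  withr::with_seed(cfg$seed, {
    w <- list()
    for (s in seq_len(cfg$n_residual_stages)) {
      cin <- if (s == 1L) 3L else K
      w[[paste0("s", s, "_W1")]] <- glorot(kk * kk * cin, K)
      w[[paste0("s", s, "_b1")]] <- numeric(K)
      w[[paste0("s", s, "_W2")]] <- glorot(kk * kk * K, K)
      w[[paste0("s", s, "_b2")]] <- numeric(K)
      w[[paste0("s", s, "_W3")]] <- glorot(kk * kk * K, K)
      w[[paste0("s", s, "_b3")]] <- numeric(K)
    }
    for (dir in c("fw", "bw")) {
      b <- numeric(4L * Hn)
      b[Hn + seq_len(Hn)] <- 1                     # forget-gate bias
      w[[paste0(dir, "_Wx")]] <- glorot(D, 4L * Hn)
      w[[paste0(dir, "_Wh")]] <- glorot(Hn, 4L * Hn)
      w[[paste0(dir, "_b")]] <- b
    }
    w$attn_Wa <- glorot(2L * Hn, cfg$d_a)
    w$attn_b <- numeric(cfg$d_a)
    w$attn_Wb <- rnorm(cfg$d_a, 0, 0.1)
    w$dense_W1 <- glorot(cfg$dense_sizes[1], 2L * Hn)
    # small positive bias keeps the ReLU level alive at initialization
    w$dense_b1 <- rep(0.1, cfg$dense_sizes[1])
    w$dense_W2 <- glorot(3L, cfg$dense_sizes[1])
    w$dense_b2 <- numeric(3L)
    w
  })
}

stage_weights <- function(w, s) {
  list(W1 = w[[paste0("s", s, "_W1")]], b1 = w[[paste0("s", s, "_b1")]],
       W2 = w[[paste0("s", s, "_W2")]], b2 = w[[paste0("s", s, "_b2")]],
       W3 = w[[paste0("s", s, "_W3")]], b3 = w[[paste0("s", s, "_b3")]])
}

lstm_weights <- function(w) {
  list(fw_Wx = w$fw_Wx, fw_Wh = w$fw_Wh, fw_b = w$fw_b,
       bw_Wx = w$bw_Wx, bw_Wh = w$bw_Wh, bw_b = w$bw_b)
}

rescnn_forward <- function(x, w, cfg, keep_cache = FALSE) {
  kk <- cfg$kernel_size
  min_t <- 2L^cfg$n_residual_stages
  if (dim(x)[1] < min_t) {
    abort(sprintf("input has %d frames; at least %d are required (%d pooling stages)",
                  dim(x)[1], min_t, cfg$n_residual_stages))
  }
  stages <- vector("list", cfg$n_residual_stages)
  h <- x
  for (s in seq_len(cfg$n_residual_stages)) {
    stages[[s]] <- stage_forward(h, stage_weights(w, s), kk)
    h <- stages[[s]]$y
  }
  seq_dims <- dim(h)
  X <- matrix(h, seq_dims[1], seq_dims[2] * seq_dims[3])
  bil <- bilstm_forward(X, lstm_weights(w))
  att <- attn_forward(bil$H, w$attn_Wa, w$attn_b, w$attn_Wb)
  den <- dense_forward(att$r, list(W1 = w$dense_W1, b1 = w$dense_b1,
                                   W2 = w$dense_W2, b2 = w$dense_b2))
  out <- list(p = den$p)
  if (keep_cache) {
    out$cache <- list(stages = stages, seq_dims = seq_dims, bil = bil,
                      att = att, den = den)
  }
  out
}

rescnn_backward <- function(y_idx, fwd, w, cfg) {
  kk <- cfg$kernel_size
  cache <- fwd$cache
  dlogits <- fwd$p
  dlogits[y_idx] <- dlogits[y_idx] - 1
  g <- list()
  db <- dense_backward(dlogits, cache$den,
                       list(W1 = w$dense_W1, W2 = w$dense_W2))
  g$dense_W1 <- db$dW1; g$dense_b1 <- db$db1
  g$dense_W2 <- db$dW2; g$dense_b2 <- db$db2
  ab <- attn_backward(db$dr, cache$att, w$attn_Wa, w$attn_Wb)
  g$attn_Wa <- ab$dWa; g$attn_b <- ab$db; g$attn_Wb <- ab$dWb
  bb <- bilstm_backward(ab$dH, cache$bil, lstm_weights(w))
  g$fw_Wx <- bb$fw_dWx; g$fw_Wh <- bb$fw_dWh; g$fw_b <- bb$fw_db
  g$bw_Wx <- bb$bw_dWx; g$bw_Wh <- bb$bw_dWh; g$bw_b <- bb$bw_db
  dh <- array(bb$dX, cache$seq_dims)
  for (s in rev(seq_len(cfg$n_residual_stages))) {
    sb <- stage_backward(dh, cache$stages[[s]], stage_weights(w, s), kk)
    g[[paste0("s", s, "_W1")]] <- sb$dW1; g[[paste0("s", s, "_b1")]] <- sb$db1
    g[[paste0("s", s, "_W2")]] <- sb$dW2; g[[paste0("s", s, "_b2")]] <- sb$db2
    g[[paste0("s", s, "_W3")]] <- sb$dW3; g[[paste0("s", s, "_b3")]] <- sb$db3
    dh <- sb$dx
  }
  g
}

#' Residual convolutional encoding of a feature tensor
#'
#' Applies the model's residual convolution stages to a t x k x 3 log-Mel
#' tensor and returns the pooled feature map flattened to a sequence over
#' time (one row per pooled frame, mel x channel features per row).
#'
#' @param F A t x k x 3 feature tensor from [stack_log_mels()].
#' @param model A fitted `rescnn` model, or a raw weight list from
#'   [rescnn_init()] (then `cfg` is required).
#' @param cfg A [rescnn_config()] when `model` is a raw weight list.
#' @return A T' x D matrix, T' = t after pooling.
#' @export
residual_conv_encode <- function(F, model, cfg = NULL) {
  w <- if (inherits(model, "rescnn")) model$weights else model
  cfg <- if (inherits(model, "rescnn")) model$cfg else cfg
  if (is.null(cfg)) abort("`cfg` required when `model` is a raw weight list")
  if (length(dim(F)) != 3 || dim(F)[3] != 3) abort("`F` must be a t x k x 3 tensor")
  min_t <- 2L^cfg$n_residual_stages
  if (dim(F)[1] < min_t) {
    abort(sprintf("input has %d frames; at least %d are required (%d pooling stages)",
                  dim(F)[1], min_t, cfg$n_residual_stages))
  }
  h <- F
  for (s in seq_len(cfg$n_residual_stages)) {
    h <- stage_forward(h, stage_weights(w, s), cfg$kernel_size)$y
  }
  d <- dim(h)
  matrix(h, d[1], d[2] * d[3])
}

#' Bidirectional LSTM encoding of a sequence
#'
#' Runs a forward and a backward LSTM over the rows of `X` and concatenates
#' the per-step hidden states, so each output row is `[h_forward, h_backward]`
#' of width twice the hidden size.
#'
#' @param X A T x D sequence matrix.
#' @param model A fitted `rescnn` model or a weight list containing
#'   `fw_Wx, fw_Wh, fw_b, bw_Wx, bw_Wh, bw_b`.
#' @return A T x (2 * hidden) matrix.
#' @export
bilstm_encode <- function(X, model) {
  if (!is.matrix(X) || nrow(X) < 1) abort("`X` must be a non-empty T x D matrix")
  w <- if (inherits(model, "rescnn")) lstm_weights(model$weights) else model
  bilstm_forward(X, w)$H
}

#' Attention pooling of a hidden-state sequence
#'
#' Scores each step as `sigmoid(h_i %*% Wa + b) . Wb`, normalizes the scores
#' with a softmax into weights `alpha`, and returns the weighted sum
#' `r = sum_i alpha_i h_i`. `r` always lies in the convex hull of the rows
#' of `H`, and `alpha` is a strictly positive probability vector.
#'
#' @param H A T x d_h matrix of hidden states.
#' @param theta A list with `Wa` (d_h x d_a), `b` (d_a), `Wb` (d_a), or a
#'   fitted `rescnn` model.
#' @return List with `r` (length d_h) and `alpha` (length T).
#' @export
attention_pool <- function(H, theta) {
  if (!is.matrix(H) || nrow(H) < 1) abort("`H` must be a non-empty T x d_h matrix")
  if (inherits(theta, "rescnn")) {
    theta <- list(Wa = theta$weights$attn_Wa, b = theta$weights$attn_b,
                  Wb = theta$weights$attn_Wb)
  }
  if (nrow(theta$Wa) != ncol(H) || length(theta$b) != ncol(theta$Wa) ||
      length(theta$Wb) != ncol(theta$Wa)) {
    abort("attention parameter dimensions do not match `H`")
  }
  out <- attn_forward(H, theta$Wa, theta$b, theta$Wb)
  list(r = out$r, alpha = out$alpha)
}

#' Two-level dense emotion classifier
#'
#' @param r Pooled representation vector.
#' @param model A fitted `rescnn` model or a weight list with
#'   `dense_W1, dense_b1, dense_W2, dense_b2`.
#' @return Named posterior probability vector over the emotions.
#' @export
classify_emotion <- function(r, model) {
  w <- if (inherits(model, "rescnn")) model$weights else model
  p <- dense_forward(r, list(W1 = w$dense_W1, b1 = w$dense_b1,
                             W2 = w$dense_W2, b2 = w$dense_b2))$p
  stats::setNames(p, EMOTIONS)
}

extract_features <- function(data, frame_p) {
  if (is.data.frame(data)) {
    if (!"waveform" %in% names(data)) {
      abort("`data` must contain a `waveform` list-column (corpus with audio)")
    }
    lapply(data$waveform, stack_log_mels, p = frame_p)
  } else if (is.list(data)) {
    data
  } else {
    abort("`data` must be an utterance tibble or a list of feature tensors")
  }
}

#' Train the emotion classifier
#'
#' Minimizes mean cross-entropy with Adam over minibatches. Training is a
#' pure function of (data, labels, cfg): initialization, shuffling and
#' updates all derive from `cfg$seed`.
#'
#' @param data An utterance tibble with a `waveform` list-column (features
#'   are extracted with [stack_log_mels()]), or a list of precomputed
#'   t x k x 3 feature tensors.
#' @param labels Emotion labels, one per training example. Every emotion
#'   class must be present.
#' @param cfg A [rescnn_config()].
#' @param frame_p [frame_params()] used for feature extraction (stored in
#'   the model and reused at prediction time).
#' @param verbose Print per-epoch loss?
#' @return An object of class `rescnn` with elements `weights`, `cfg`,
#'   `frame_params`, `levels` and `log` (tibble of per-epoch mean loss).
#' @export
train_rescnn <- function(data, labels, cfg = rescnn_config(),
                         frame_p = frame_params(), verbose = FALSE) {
  feats <- extract_features(data, frame_p)
  labels <- as.character(labels)
  if (length(feats) != length(labels)) abort("one label per training example required")
  missing_cls <- setdiff(EMOTIONS, labels)
  if (length(missing_cls) > 0) {
    abort(sprintf("class '%s' is absent from the training data", missing_cls[1]))
  }
  if (!all(labels %in% EMOTIONS)) abort("labels outside the emotion vocabulary")
  y <- match(labels, EMOTIONS)
  n_mel <- dim(feats[[1]])[2]
  n <- length(feats)

  w <- rescnn_init(cfg, n_mel)
  m <- lapply(w, function(x) x * 0)
  v <- lapply(w, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  adam_t <- 0L
  log_rows <- vector("list", cfg$epochs)
  best <- Inf; stall <- 0L; epochs_run <- 0L

  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        gsum <- NULL
        for (i in idx) {
          fwd <- rescnn_forward(feats[[i]], w, cfg, keep_cache = TRUE)
          losses[i] <- -log(max(fwd$p[y[i]], 1e-12))
          g <- rescnn_backward(y[i], fwd, w, cfg)
          gsum <- if (is.null(gsum)) g else Map(`+`, gsum, g)
        }
        gsum <- lapply(gsum, `/`, length(idx))
        adam_t <- adam_t + 1L
        for (nm in names(w)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gsum[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gsum[[nm]]^2
          mh <- m[[nm]] / (1 - b1^adam_t)
          vh <- v[[nm]] / (1 - b2^adam_t)
          w[[nm]] <- w[[nm]] - cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      ep_loss <- mean(losses)
      log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss)
      epochs_run <- ep
      if (verbose) message(sprintf("epoch %2d  loss %.4f", ep, ep_loss))
      if (best - ep_loss < cfg$min_delta) stall <- stall + 1L else stall <- 0L
      best <- min(best, ep_loss)
      if (stall >= cfg$patience) break
    }
  })

  structure(list(
    weights = w, cfg = cfg, frame_params = frame_p, levels = EMOTIONS,
    n_mel = n_mel, log = dplyr::bind_rows(log_rows[seq_len(epochs_run)])
  ), class = "rescnn")
}

#' @export
print.rescnn <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<rescnn> %d stages x %d kernels, lstm %d, %s parameters\n",
              x$cfg$n_residual_stages, x$cfg$n_kernels, x$cfg$lstm_hidden,
              format(np, big.mark = ",")))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              nrow(x$log), tail(x$log$loss, 1)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rescnn <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.rescnn <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    final_loss = tail(x$log$loss, 1),
    n_parameters = sum(vapply(x$weights, length, integer(1))),
    n_kernels = x$cfg$n_kernels,
    lstm_hidden = x$cfg$lstm_hidden
  )
}

#' Predict the emotion of one utterance
#'
#' @param w A `waveform`.
#' @param model A fitted `rescnn` model.
#' @return List with `label` (the argmax emotion) and `posterior` (named
#'   probability vector).
#' @export
predict_utterance <- function(w, model) {
  stopifnot(inherits(model, "rescnn"))
  F <- stack_log_mels(w, model$frame_params)
  p <- rescnn_forward(F, model$weights, model$cfg)$p
  list(label = EMOTIONS[which.max(p)], posterior = stats::setNames(p, EMOTIONS))
}

#' Predict emotions for every utterance of a corpus table
#'
#' @param data Utterance tibble with a `waveform` list-column.
#' @param model A fitted `rescnn` model.
#' @return The input tibble with columns `pred_emotion`, `p_angry`,
#'   `p_neutral`, `p_fear` appended.
#' @export
predict_utterances <- function(data, model) {
  stopifnot(is.data.frame(data), inherits(model, "rescnn"))
  if (!"waveform" %in% names(data)) abort("`data` must contain a `waveform` list-column")
  preds <- lapply(data$waveform, predict_utterance, model = model)
  post <- do.call(rbind, lapply(preds, `[[`, "posterior"))
  data$pred_emotion <- vapply(preds, `[[`, character(1), "label")
  data$p_angry <- post[, "angry"]
  data$p_neutral <- post[, "neutral"]
  data$p_fear <- post[, "fear"]
  data
}
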