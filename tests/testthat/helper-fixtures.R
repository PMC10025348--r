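# Shared fixtures: a scaled-down model configuration for desk-scale training
# runs, a balanced synthetic tone corpus, and a cache so the expensive
# trained model is fitted once and reused across test files.

test_frame_params <- function() frame_params(n_mel = 32)

test_cfg <- function(seed = 42L, epochs = 15L) {
  rescnn_config(n_kernels = 24L, lstm_hidden = 24L, d_a = 16L,
                dense_sizes = c(32L, 3L), epochs = epochs, seed = seed)
}

tiny_cfg <- function(seed = 7L, ...) {
  rescnn_config(n_kernels = 3L, n_residual_stages = 2L, lstm_hidden = 4L,
                d_a = 3L, dense_sizes = c(5L, 3L), seed = seed, ...)
}

# balanced 3-class tone corpus: n_per_class utterances per emotion, 1 s each,
# random roles, deterministic in seed0
make_tone_set <- function(n_per_class, seed0, params = court_params()) {
  labs <- rep(EMOTIONS, each = n_per_class)
  roles <- withr::with_seed(seed0, sample(ROLES, length(labs), replace = TRUE))
  wavs <- lapply(seq_along(labs), function(i) {
    synthesize_utterance(labs[i], roles[i], 1.0, params,
                         seed = seed0 * 1000L + i)
  })
  list(waveforms = wavs, labels = labs, roles = roles)
}

.fixture_cache <- new.env(parent = emptyenv())

# 150-utterance training set / 60-utterance held-out set, features extracted
# once
tone_corpus <- function() {
  if (is.null(.fixture_cache$tone)) {
    fp <- test_frame_params()
    tr <- make_tone_set(50, seed0 = 11)
    te <- make_tone_set(20, seed0 = 99)
    .fixture_cache$tone <- list(
      train_x = lapply(tr$waveforms, stack_log_mels, p = fp),
      train_y = tr$labels,
      test_x = lapply(te$waveforms, stack_log_mels, p = fp),
      test_y = te$labels,
      fp = fp
    )
  }
  .fixture_cache$tone
}

# the model shared by the learning and end-to-end audio checks
trained_model <- function() {
  if (is.null(.fixture_cache$model)) {
    tc <- tone_corpus()
    .fixture_cache$model <- train_rescnn(tc$train_x, tc$train_y,
                                         cfg = test_cfg(), frame_p = tc$fp)
  }
  .fixture_cache$model
}

predict_features <- function(feats, model) {
  vapply(feats, function(f) {
    EMOTIONS[which.max(courttone:::rescnn_forward(f, model$weights, model$cfg)$p)]
  }, character(1))
}

# autocorrelation-based pitch estimator, the oracle for the synthesizer
estimate_f0 <- function(samples, sample_rate, f_min = 60, f_max = 400) {
  ac <- stats::acf(samples, lag.max = ceiling(sample_rate / f_min),
                   plot = FALSE)$acf[-1]
  lags <- seq_along(ac)
  ok <- lags >= floor(sample_rate / f_max) & lags <= ceiling(sample_rate / f_min)
  sample_rate / lags[ok][which.max(ac[ok])]
}

# literal evaluation of the delta regression formula with replicate padding
brute_force_delta <- function(f, N) {
  t_n <- nrow(f); k <- ncol(f)
  out <- matrix(0, t_n, k)
  denom <- 2 * sum((1:N)^2)
  for (j in seq_len(t_n)) {
    for (b in seq_len(k)) {
      acc <- 0
      for (n in seq_len(N)) {
        acc <- acc + n * (f[min(j + n, t_n), b] - f[max(j - n, 1), b])
      }
      out[j, b] <- acc / denom
    }
  }
  out
}

# merge ground-truth utterance intervals separated by less than the silence
# threshold: the spans segmentation is expected to return
merge_truth_spans <- function(truth, thr = 1.0) {
  truth <- truth[order(truth$start_s), ]
  s <- truth$start_s[1]; e <- truth$end_s[1]
  out <- list()
  for (i in seq_len(nrow(truth))[-1]) {
    if (truth$start_s[i] - e < thr) {
      e <- truth$end_s[i]
    } else {
      out[[length(out) + 1]] <- c(s, e)
      s <- truth$start_s[i]; e <- truth$end_s[i]
    }
  }
  out[[length(out) + 1]] <- c(s, e)
  m <- do.call(rbind, out)
  tibble::tibble(start_s = m[, 1], end_s = m[, 2])
}
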