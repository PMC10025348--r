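#' Framing and log-Mel feature parameters
#'
#' @param window_s Analysis window length in seconds (default 25 ms).
#' @param hop_s Hop (stride) between windows in seconds (default 10 ms).
#' @param n_mel Number of triangular mel bands k (default 64).
#' @param delta_width Regression half-width N of the delta filter (default 2).
#' @param log_floor Value added to band energies before the (natural) log,
#'   so silence maps to `log(log_floor)` instead of -Inf.
#' @return A list of class `frame_params`.
#' @export
frame_params <- function(window_s = 0.025, hop_s = 0.010, n_mel = 64L,
                         delta_width = 2L, log_floor = 1e-10) {
  if (hop_s <= 0 || window_s <= 0 || hop_s > window_s) {
    abort("need 0 < hop_s <= window_s")
  }
  if (n_mel < 1) abort("`n_mel` must be >= 1")
  if (delta_width < 1) abort("`delta_width` must be >= 1")
  structure(list(window_s = window_s, hop_s = hop_s, n_mel = as.integer(n_mel),
                 delta_width = as.integer(delta_width), log_floor = log_floor),
            class = "frame_params")
}

as_waveform <- function(w, sample_rate = NULL) {
  if (inherits(w, "waveform")) return(w)
  if (is.numeric(w) && !is.null(sample_rate)) return(waveform(w, sample_rate))
  abort("expected a `waveform` (or a numeric vector plus `sample_rate`)")
}

#' Z-score normalize a waveform
#'
#' Centres and scales the samples to mean 0 and (sample) standard deviation
#' 1. A constant input has no scale; it is returned as all zeros with a
#' warning.
#'
#' @param w A `waveform` (or numeric vector, with `sample_rate`).
#' @param sample_rate Sample rate, required when `w` is a bare vector.
#' @return A `waveform` with normalized samples.
#' @export
znormalize <- function(w, sample_rate = NULL) {
  w <- as_waveform(w, sample_rate)
  x <- w$samples
  if (length(x) < 2) abort("need at least 2 samples to normalize")
  s <- sd(x)
  if (s == 0 || !is.finite(s)) {
    warn("constant waveform: z-normalization returns all zeros")
    return(waveform(rep(0, length(x)), w$sample_rate))
  }
  waveform((x - mean(x)) / s, w$sample_rate)
}

#' Slice a waveform into tapered analysis frames
#'
#' Frame j (0-based) covers samples `[j*hop, j*hop + win)`; the frame count
#' is `floor((L - win) / hop) + 1`. A Hamming taper is applied to each frame.
#'
#' @inheritParams znormalize
#' @param p A [frame_params()] object.
#' @return A t x win matrix of windowed frames, with attributes `hop`,
#'   `win` (samples) and `sample_rate`.
#' @export
frame_signal <- function(w, p = frame_params(), sample_rate = NULL) {
  w <- as_waveform(w, sample_rate)
  win <- as.integer(round(p$window_s * w$sample_rate))
  hop <- as.integer(round(p$hop_s * w$sample_rate))
  L <- length(w$samples)
  if (L < win) {
    abort(sprintf("waveform (%d samples) shorter than one %d-sample window", L, win))
  }
  t_frames <- (L - win) %/% hop + 1L
  idx <- outer(seq_len(win), (seq_len(t_frames) - 1L) * hop, `+`)
  frames <- t(matrix(w$samples[idx], nrow = win))
  taper <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  frames <- sweep(frames, 2, taper, `*`)
  attr(frames, "hop") <- hop
  attr(frames, "win") <- win
  attr(frames, "sample_rate") <- w$sample_rate
  frames
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank matrix
#'
#' @param n_mel Number of mel bands.
#' @param n_fft DFT size.
#' @param sample_rate Sample rate in Hz.
#' @return An `(n_fft/2 + 1) x n_mel` matrix of triangular weights.
#' @export
mel_filterbank <- function(n_mel, n_fft, sample_rate) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2), length.out = n_mel + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_bins, n_mel)
  for (m in seq_len(n_mel)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

#' Log-mel spectrogram of framed audio
#'
#' Per frame: DFT (zero-padded to the next power of two), power spectrum,
#' triangular mel-band energies `q_j`, then `f_j = log(q_j + log_floor)`
#' (natural log). All entries are finite by construction.
#'
#' @param frames Output of [frame_signal()].
#' @param p A [frame_params()] object.
#' @return A t x n_mel matrix of log mel-band energies.
#' @export
log_mel_spectrogram <- function(frames, p = frame_params()) {
  sr <- attr(frames, "sample_rate")
  win <- attr(frames, "win")
  if (is.null(sr) || is.null(win)) abort("`frames` must come from frame_signal()")
  n_fft <- next_pow2(win)
  n_bins <- n_fft %/% 2L + 1L
  padded <- cbind(frames, matrix(0, nrow(frames), n_fft - win))
  spec <- stats::mvfft(t(padded))[seq_len(n_bins), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2                      # n_bins x t
  fb <- mel_filterbank(p$n_mel, n_fft, sr)
  q <- crossprod(power, fb)                             # t x n_mel
  log(q + p$log_floor)
}

#' Delta (regression slope) features
#'
#' Computes the standard regression-based temporal derivative per mel band:
#' `d_j = sum_{n=1..N} n (f_{j+n} - f_{j-n}) / (2 sum_{n=1..N} n^2)`,
#' with replicate padding of the first and last frames at the boundaries.
#'
#' @param f A t x k feature matrix.
#' @param N Regression half-width (>= 1).
#' @return A t x k matrix of deltas.
#' @export
delta_features <- function(f, N = 2L) {
  if (N < 1) abort("`N` must be >= 1")
  f <- as.matrix(f)
  t_n <- nrow(f)
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, t_n, ncol(f))
  for (n in seq_len(N)) {
    fwd <- f[pmin(seq_len(t_n) + n, t_n), , drop = FALSE]
    bwd <- f[pmax(seq_len(t_n) - n, 1L), , drop = FALSE]
    out <- out + n * (fwd - bwd)
  }
  out / denom
}

#' Stacked log-Mel feature tensor (static, delta, delta-delta)
#'
#' The full feature front end: z-score normalization, 25 ms / 10 ms Hamming
#' framing, log-mel spectrogram, then the delta and delta-delta channels.
#' The result is the t x k x 3 tensor the classifier consumes.
#'
#' @inheritParams znormalize
#' @param p A [frame_params()] object.
#' @return A t x k x 3 array with `dimnames` channel labels
#'   `c("static", "delta", "delta_delta")` on the third axis.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, length.out = 16000)), 16000)
#' dim(stack_log_mels(w)) # 98 x 64 x 3
#' @export
stack_log_mels <- function(w, p = frame_params(), sample_rate = NULL) {
  w <- znormalize(as_waveform(w, sample_rate))
  frames <- frame_signal(w, p)
  f <- log_mel_spectrogram(frames, p)
  d <- delta_features(f, p$delta_width)
  dd <- delta_features(d, p$delta_width)
  out <- array(c(f, d, dd), dim = c(nrow(f), ncol(f), 3L))
  dimnames(out) <- list(NULL, NULL, c("static", "delta", "delta_delta"))
  out
}
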