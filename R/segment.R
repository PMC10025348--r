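#' Segment a session recording at long silences
#'
#' Short-time RMS energy is computed over 25 ms frames (10 ms hop); frames
#' below an adaptive threshold - `max(abs_floor, rel_frac` times the 95th
#' percentile frame RMS`)` - are silence. Any maximal silent run lasting at
#' least `gap_threshold_s` (default 1 s) terminates the current utterance;
#' shorter pauses are kept inside the utterance. Segments shorter than
#' `min_duration_s` are dropped.
#'
#' @param w A `waveform` (or numeric vector plus `sample_rate`).
#' @param gap_threshold_s Silence duration that splits utterances (default 1 s).
#' @param min_duration_s Minimum utterance duration retained (default 0.3 s).
#' @param rel_frac Relative energy threshold as a fraction of the 95th
#'   percentile frame RMS (default 0.05).
#' @param abs_floor Absolute RMS floor under which a frame is always silent.
#' @param sample_rate Required when `w` is a bare numeric vector.
#' @return A tibble with columns `start_s`, `end_s`; zero rows for an
#'   all-silent input. Spans are ordered and non-overlapping.
#' @examples
#' p <- court_params()
#' u <- synthesize_utterance("neutral", "judge", 1, p, seed = 1)$samples
#' s <- c(u, numeric(1.5 * 16000), u) # two tones, 1.5 s apart
#' segment_by_silence(waveform(s, 16000))
#' @export
segment_by_silence <- function(w, gap_threshold_s = 1.0, min_duration_s = 0.3,
                               rel_frac = 0.05, abs_floor = 1e-4,
                               sample_rate = NULL) {
  w <- as_waveform(w, sample_rate)
  sr <- w$sample_rate
  win <- as.integer(round(0.025 * sr))
  hop <- as.integer(round(0.010 * sr))
  x <- w$samples
  if (length(x) < win) x <- c(x, numeric(win - length(x)))
  t_frames <- (length(x) - win) %/% hop + 1L
  idx <- outer(seq_len(win), (seq_len(t_frames) - 1L) * hop, `+`)
  rms <- sqrt(colMeans(matrix(x[idx]^2, nrow = win)))
  thr <- max(abs_floor, rel_frac * quantile(rms, 0.95, names = FALSE))
  voiced <- rms >= thr
  if (!any(voiced)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  # merge voiced runs separated by silences shorter than the gap threshold;
  # a silent run of m frames spans m*hop + (win - hop) samples of audio
  r <- rle(voiced)
  ends_f <- cumsum(r$lengths)
  starts_f <- ends_f - r$lengths + 1L
  gap_frames <- ceiling((gap_threshold_s * sr - (win - hop)) / hop)
  n_runs <- length(r$values)
  seg_start <- integer(0); seg_end <- integer(0)
  open <- FALSE; cur_start <- NA_integer_; cur_end <- NA_integer_
  for (i in seq_len(n_runs)) {
    if (r$values[i]) {
      if (!open) { cur_start <- starts_f[i]; open <- TRUE }
      cur_end <- ends_f[i]
    } else if (open && r$lengths[i] >= gap_frames) {
      seg_start <- c(seg_start, cur_start); seg_end <- c(seg_end, cur_end)
      open <- FALSE
    }
  }
  if (open) { seg_start <- c(seg_start, cur_start); seg_end <- c(seg_end, cur_end) }
  # sample-level boundary refinement: walk out from the coarse frame bounds
  # along a 5 ms amplitude envelope
  x_full <- abs(w$samples)
  env <- as.numeric(stats::filter(x_full, rep(1 / (0.005 * sr), round(0.005 * sr)),
                                  sides = 2))
  env[is.na(env)] <- 0
  # mean-|x| envelope of a tone sits below its RMS, and utterance edges ramp
  # up from zero, so refine with a slightly lower threshold than the frame
  # detector uses
  amp_thr <- 0.5 * thr
  n_samp <- length(w$samples)
  start_s <- numeric(length(seg_start)); end_s <- numeric(length(seg_start))
  for (k in seq_along(seg_start)) {
    s0 <- (seg_start[k] - 1L) * hop + 1L
    e0 <- min((seg_end[k] - 1L) * hop + win, n_samp)
    lo <- max(1L, s0 - win); hi <- min(n_samp, e0 + win)
    above <- which(env[lo:hi] >= amp_thr)
    if (length(above) > 0) {
      start_s[k] <- (lo + above[1] - 2L) / sr
      end_s[k] <- (lo + above[length(above)] - 1L) / sr
    } else {
      start_s[k] <- (s0 - 1L) / sr
      end_s[k] <- e0 / sr
    }
  }
  keep_seg <- (end_s - start_s) >= min_duration_s
  tibble::tibble(start_s = start_s[keep_seg], end_s = end_s[keep_seg])
}

#' Attach speaker roles to segmented spans
#'
#' Each detected span receives the role of the metadata interval with which
#' it overlaps most (ties broken by the earlier metadata interval). Spans
#' overlapping no interval are excluded with a warning reporting the count.
#'
#' @param spans Tibble with `start_s`, `end_s` (from [segment_by_silence()]).
#' @param role_metadata Tibble with `role`, `start_s`, `end_s` (and
#'   optionally `record_id`) describing who speaks when.
#' @return A tibble of utterances: `utterance_id`, `role`, `start_s`,
#'   `end_s` (plus `record_id` when present in the metadata).
#' @export
assign_roles <- function(spans, role_metadata) {
  stopifnot(is.data.frame(spans), is.data.frame(role_metadata))
  if (!all(c("start_s", "end_s") %in% names(spans))) {
    abort("`spans` needs columns start_s, end_s")
  }
  if (!all(c("role", "start_s", "end_s") %in% names(role_metadata))) {
    abort("`role_metadata` needs columns role, start_s, end_s")
  }
  n <- nrow(spans)
  role <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ov <- pmin(spans$end_s[i], role_metadata$end_s) -
      pmax(spans$start_s[i], role_metadata$start_s)
    if (all(ov <= 0)) next
    j <- which.max(ov)         # which.max returns the earliest maximal interval
    role[i] <- role_metadata$role[j]
    keep[i] <- TRUE
  }
  if (any(!keep)) {
    warn(sprintf("%d span(s) overlapped no role interval and were excluded",
                 sum(!keep)))
  }
  out <- spans[keep, , drop = FALSE]
  out$role <- role[keep]
  if ("record_id" %in% names(role_metadata) && nrow(out) > 0) {
    out$record_id <- role_metadata$record_id[1]
  }
  out$utterance_id <- seq_len(nrow(out))
  tibble::as_tibble(out[, c(intersect("record_id", names(out)),
                            "utterance_id", "role", "start_s", "end_s")])
}
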