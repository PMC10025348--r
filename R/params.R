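#' Default per-emotion acoustic profiles
#'
#' Each emotion is realised acoustically through a small set of voice-source
#' parameters: mean fundamental frequency (`f0_mean`, Hz), the standard
#' deviation of its slow drift (`f0_sd`, Hz), cycle-to-cycle pitch jitter as a
#' fraction of f0 (`jitter`), an overall amplitude gain (`rms_gain`), and the
#' syllable-rate amplitude modulation frequency (`syllable_rate`, Hz). The
#' defaults give three separable but overlapping classes: anger is loud, high
#' and fast; fear is quiet, breathy (jittery) and unstable in pitch; neutral
#' speech sits in between.
#'
#' @return A named list (one entry per emotion) of acoustic parameter lists.
#' @export
default_acoustic_profile <- function() {
  list(
    angry   = list(f0_mean = 170, f0_sd = 15, jitter = 0.00, rms_gain = 2.0,
                   syllable_rate = 5.2),
    neutral = list(f0_mean = 120, f0_sd = 8,  jitter = 0.00, rms_gain = 1.0,
                   syllable_rate = 4.0),
    fear    = list(f0_mean = 155, f0_sd = 30, jitter = 0.03, rms_gain = 0.7,
                   syllable_rate = 4.0)
  )
}

# Small additive f0 offsets (Hz) distinguishing speakers by role.
role_f0_offset <- c(judge = -10, plaintiff = 0, defendant = 8)

#' Parameters of the synthetic courtroom corpus generator
#'
#' Bundles every knob of the generator into a validated parameter object.
#' The defaults encode the study conditions the pipeline is designed around:
#' 50 court hearing records, a judge voicing only anger or neutrality, a
#' plaintiff voicing all three emotions, a planted judge-to-defendant
#' influence matrix, and a defendant logic flag driven by the dominant
#' courtroom emotion. Default conditional probabilities are the row
#' proportions of the published 50-record cross-tabulations (see
#' [court_tables()]).
#'
#' The generative dependence structure is judge -> defendant; the plaintiff's
#' emotion is drawn independently from its prior. `defendant_given_plaintiff`
#' is retained for alternative scenarios (set `plaintiff_drives = TRUE` in
#' [sample_corpus()]'s params to use it instead).
#'
#' @param n_records Number of court records (sessions) to generate.
#' @param judge_emotion_prior Probability vector over (angry, neutral).
#' @param plaintiff_emotion_prior Probability vector over (angry, neutral, fear).
#' @param defendant_given_judge 2x3 row-stochastic matrix: rows judge
#'   (angry, neutral), columns defendant (angry, neutral, fear).
#' @param defendant_given_plaintiff 3x3 row-stochastic matrix, used only in
#'   the alternative plaintiff-driven scenario.
#' @param logic_given_court_emotion Probability that the defendant is
#'   "logical" given each courtroom emotion (angry, neutral, fear).
#' @param utterances_per_role Integer range (min, max) of utterances per role
#'   per record.
#' @param utterance_duration_s Numeric range (min, max) of utterance duration
#'   in seconds.
#' @param inter_utterance_gap_s Numeric range (min, max) of silence between
#'   consecutive utterances in seconds; must straddle the 1 s segmentation
#'   threshold so both merge and split behaviour occur.
#' @param annotator_error_rate Probability that a simulated annotator reports
#'   a wrong label (uniform over the other two emotions).
#' @param acoustic_profile Per-emotion acoustic parameters, see
#'   [default_acoustic_profile()].
#' @param sample_rate Audio sample rate in Hz.
#' @param seed Integer seed; the corpus is a pure function of (params, seed).
#'
#' @return An object of class `court_params`.
#' @examples
#' p <- court_params(n_records = 4, seed = 42)
#' p$defendant_given_judge
#' @export
court_params <- function(n_records = 50,
                         judge_emotion_prior = c(angry = 21 / 50, neutral = 29 / 50),
                         plaintiff_emotion_prior = c(angry = 16 / 50, neutral = 30 / 50, fear = 4 / 50),
                         defendant_given_judge = matrix(
                           c(10, 1, 10, 8, 19, 2) / c(21, 21, 21, 29, 29, 29),
                           nrow = 2, byrow = TRUE,
                           dimnames = list(c("angry", "neutral"), EMOTIONS)
                         ),
                         defendant_given_plaintiff = matrix(
                           c(7, 3, 6, 10, 16, 4, 1, 1, 2) / c(16, 16, 16, 30, 30, 30, 4, 4, 4),
                           nrow = 3, byrow = TRUE,
                           dimnames = list(EMOTIONS, EMOTIONS)
                         ),
                         logic_given_court_emotion = c(angry = 1 / 16, neutral = 28 / 32, fear = 1 / 2),
                         utterances_per_role = c(3L, 6L),
                         utterance_duration_s = c(1.0, 2.5),
                         inter_utterance_gap_s = c(0.4, 1.6),
                         annotator_error_rate = 0.1,
                         acoustic_profile = default_acoustic_profile(),
                         sample_rate = 16000,
                         seed = 1L) {
  p <- structure(
    list(
      n_records = as.integer(n_records),
      judge_emotion_prior = judge_emotion_prior,
      plaintiff_emotion_prior = plaintiff_emotion_prior,
      defendant_given_judge = defendant_given_judge,
      defendant_given_plaintiff = defendant_given_plaintiff,
      logic_given_court_emotion = logic_given_court_emotion,
      utterances_per_role = as.integer(utterances_per_role),
      utterance_duration_s = utterance_duration_s,
      inter_utterance_gap_s = inter_utterance_gap_s,
      annotator_error_rate = annotator_error_rate,
      acoustic_profile = acoustic_profile,
      sample_rate = sample_rate,
      seed = as.integer(seed)
    ),
    class = "court_params"
  )
  validate_court_params(p)
  p
}

check_prob_vec <- function(x, what, n) {
  if (length(x) != n || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be %d probabilities in [0, 1]", what, n))
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(sprintf("`%s` must sum to 1 (got %.12f)", what, sum(x)))
  }
  invisible(x)
}

check_stochastic_matrix <- function(m, what, nr, nc) {
  if (!is.matrix(m) || nrow(m) != nr || ncol(m) != nc) {
    abort(sprintf("`%s` must be a %dx%d matrix", what, nr, nc))
  }
  for (i in seq_len(nr)) check_prob_vec(m[i, ], sprintf("%s[%d, ]", what, i), nc)
  invisible(m)
}

validate_court_params <- function(p) {
  stopifnot(inherits(p, "court_params"))
  if (p$n_records < 1L) abort("`n_records` must be >= 1")
  check_prob_vec(p$judge_emotion_prior, "judge_emotion_prior", 2)
  check_prob_vec(p$plaintiff_emotion_prior, "plaintiff_emotion_prior", 3)
  check_stochastic_matrix(p$defendant_given_judge, "defendant_given_judge", 2, 3)
  check_stochastic_matrix(p$defendant_given_plaintiff, "defendant_given_plaintiff", 3, 3)
  if (length(p$logic_given_court_emotion) != 3 ||
      any(p$logic_given_court_emotion < 0) || any(p$logic_given_court_emotion > 1)) {
    abort("`logic_given_court_emotion` must be 3 probabilities in [0, 1]")
  }
  if (length(p$utterances_per_role) != 2 || p$utterances_per_role[1] < 1 ||
      p$utterances_per_role[2] < p$utterances_per_role[1]) {
    abort("`utterances_per_role` must be an increasing range with min >= 1")
  }
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] >= r[1]
  if (!rng_ok(p$utterance_duration_s)) abort("`utterance_duration_s` must be a positive range")
  if (!rng_ok(p$inter_utterance_gap_s)) abort("`inter_utterance_gap_s` must be a positive range")
  if (p$inter_utterance_gap_s[1] >= 1 || p$inter_utterance_gap_s[2] <= 1) {
    abort("`inter_utterance_gap_s` must straddle the 1 s segmentation threshold")
  }
  if (p$annotator_error_rate < 0 || p$annotator_error_rate >= 1) {
    abort("`annotator_error_rate` must be in [0, 1)")
  }
  for (e in EMOTIONS) {
    prof <- p$acoustic_profile[[e]]
    if (is.null(prof)) abort(sprintf("acoustic_profile is missing emotion '%s'", e))
    need <- c("f0_mean", "f0_sd", "jitter", "rms_gain", "syllable_rate")
    if (!all(need %in% names(prof))) {
      abort(sprintf("acoustic_profile$%s must contain %s", e, paste(need, collapse = ", ")))
    }
  }
  if (p$sample_rate <= 0) abort("`sample_rate` must be positive")
  invisible(p)
}

#' @export
print.court_params <- function(x, ...) {
  cat("<court_params>\n")
  cat("  records:", x$n_records, " sample rate:", x$sample_rate, "Hz  seed:", x$seed, "\n")
  cat("  utterances/role:", paste(x$utterances_per_role, collapse = "-"),
      " duration:", paste(x$utterance_duration_s, collapse = "-"), "s",
      " gap:", paste(x$inter_utterance_gap_s, collapse = "-"), "s\n")
  cat("  annotator error rate:", x$annotator_error_rate, "\n")
  cat("  defendant | judge:\n")
  print(round(x$defendant_given_judge, 3))
  invisible(x)
}
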