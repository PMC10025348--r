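#' Synthesize one emotion-conditioned utterance
#'
#' Renders a voiced utterance as a harmonic source following a fundamental
#' frequency (f0) contour, with slow f0 drift, optional cycle-level jitter,
#' syllable-rate amplitude modulation and a low-level noise floor. The
#' emotion determines the acoustic parameters (see
#' [default_acoustic_profile()]); the role adds a small constant f0 offset so
#' speakers differ systematically from one another.
#'
#' There is no phonetic or language content: the generator targets the
#' prosodic cues (pitch level and variability, loudness, speaking rate,
#' voice stability) that carry vocal emotion, not intelligible speech.
#'
#' @param emotion One of `"angry"`, `"neutral"`, `"fear"`.
#' @param role One of `"judge"`, `"plaintiff"`, `"defendant"`.
#' @param duration_s Utterance duration in seconds (> 0).
#' @param params A [court_params()] object.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return A `waveform`: list with `samples` (numeric) and `sample_rate`.
#' @examples
#' p <- court_params()
#' w <- synthesize_utterance("angry", "judge", 1.0, p, seed = 7)
#' length(w$samples) # 16000
#' @export
synthesize_utterance <- function(emotion, role, duration_s, params, seed) {
  emotion <- match.arg(emotion, EMOTIONS)
  role <- match.arg(role, ROLES)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive")
  }
  prof <- params$acoustic_profile[[emotion]]
  sr <- params$sample_rate
  n <- as.integer(round(duration_s * sr))
  withr::with_seed(as.integer(seed), {
    tt <- seq_len(n) / sr
    # slow pitch drift: ~4 control points per second, interpolated
    k_drift <- max(4L, ceiling(duration_s * 4) + 1L)
    drift <- approx(seq(0, duration_s, length.out = k_drift),
                    rnorm(k_drift, 0, prof$f0_sd), xout = tt, rule = 2)$y
    # jitter: fast perturbation of the instantaneous f0, ~100 Hz control rate
    if (prof$jitter > 0) {
      k_jit <- ceiling(duration_s * 100) + 1L
      jit <- approx(seq(0, duration_s, length.out = k_jit),
                    rnorm(k_jit, 0, prof$jitter * prof$f0_mean), xout = tt,
                    rule = 2)$y
    } else {
      jit <- 0
    }
    f0 <- pmax(40, prof$f0_mean + role_f0_offset[[role]] + drift + jit)
    phase <- 2 * pi * cumsum(f0) / sr
    sig <- numeric(n)
    phases <- runif(6, 0, 2 * pi)
    for (h in 1:6) sig <- sig + 0.7^(h - 1) * sin(h * phase + phases[h])
    # syllable-rate amplitude modulation
    env <- 0.55 + 0.45 * sin(2 * pi * prof$syllable_rate * tt + runif(1, 0, 2 * pi))
    sig <- sig * env
    # 20 ms onset/offset ramps to avoid clicks
    ramp_n <- min(n, as.integer(0.020 * sr))
    if (ramp_n > 1) {
      ramp <- seq(0, 1, length.out = ramp_n)
      sig[seq_len(ramp_n)] <- sig[seq_len(ramp_n)] * ramp
      sig[(n - ramp_n + 1):n] <- sig[(n - ramp_n + 1):n] * rev(ramp)
    }
    sig <- sig / max(sqrt(mean(sig^2)), 1e-12)       # unit RMS
    sig <- 0.1 * prof$rms_gain * sig + rnorm(n, 0, 0.005)
    waveform(sig, sr)
  })
}

#' Construct a waveform object
#'
#' @param samples Numeric sample vector.
#' @param sample_rate Sample rate in Hz.
#' @return A list of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1, sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Simulate three noisy expert annotators
#'
#' Each of three simulated annotators independently reports the true emotion
#' with probability `1 - error_rate` and otherwise one of the other two
#' emotions uniformly at random.
#'
#' @param true_label The true emotion label.
#' @param error_rate Annotator error probability in [0, 1).
#' @param seed Integer seed.
#' @return Character vector of three emotion labels.
#' @examples
#' simulate_annotators("fear", error_rate = 0, seed = 1) # all "fear"
#' @export
simulate_annotators <- function(true_label, error_rate, seed) {
  true_label <- match.arg(true_label, EMOTIONS)
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1)")
  withr::with_seed(as.integer(seed), draw_annotators(true_label, error_rate))
}

# unseeded core, used inside sample_corpus()'s single RNG stream
draw_annotators <- function(true_label, error_rate) {
  others <- setdiff(EMOTIONS, true_label)
  vapply(1:3, function(i) {
    if (runif(1) < error_rate) sample(others, 1) else true_label
  }, character(1))
}

sample_cat <- function(levels, probs) {
  levels[sample.int(length(levels), 1, prob = probs)]
}

#' Generate a synthetic courtroom corpus with planted ground truth
#'
#' Draws `params$n_records` court sessions. Per record: the judge's emotion
#' comes from its prior, the plaintiff's emotion is drawn independently, and
#' the defendant's emotion is drawn from `defendant_given_judge` conditioned
#' on the judge (the planted causal edge). The dominant non-defendant
#' ("court") emotion then drives the defendant's logic flag. Every utterance
#' of a role carries that role's record-level emotion, and three simulated
#' annotators label each utterance.
#'
#' Utterances are laid out on a session timeline separated by silences drawn
#' from `inter_utterance_gap_s`, which straddles the 1 s segmentation
#' threshold. With `audio = TRUE` each utterance is synthesized with
#' [synthesize_utterance()]; with `audio = FALSE` only the label/metadata
#' tables are produced (useful for large label-level simulations).
#'
#' @param params A [court_params()] object.
#' @param audio Synthesize waveforms? Default `TRUE`.
#' @param driver `"judge"` (default) draws the defendant's emotion from the
#'   judge; `"plaintiff"` is the alternative scenario using
#'   `defendant_given_plaintiff`.
#' @return A `court_corpus`: list with `utterances` (tibble; one row per
#'   utterance, with a `waveform` list-column when `audio = TRUE`),
#'   `records` (tibble; one row per record with the planted role emotions,
#'   court emotion and logic flag) and `params`.
#' @examples
#' corp <- sample_corpus(court_params(n_records = 2, seed = 3), audio = FALSE)
#' corp$records
#' @export
sample_corpus <- function(params, audio = TRUE, driver = c("judge", "plaintiff")) {
  validate_court_params(params)
  driver <- match.arg(driver)
  withr::with_seed(params$seed, {
    rec_rows <- vector("list", params$n_records)
    utt_rows <- vector("list", params$n_records)
    for (r in seq_len(params$n_records)) {
      judge_e <- sample_cat(c("angry", "neutral"), params$judge_emotion_prior)
      plaintiff_e <- sample_cat(EMOTIONS, params$plaintiff_emotion_prior)
      defendant_e <- if (driver == "judge") {
        sample_cat(EMOTIONS, params$defendant_given_judge[judge_e, ])
      } else {
        sample_cat(EMOTIONS, params$defendant_given_plaintiff[plaintiff_e, ])
      }
      role_emotion <- c(judge = judge_e, plaintiff = plaintiff_e,
                        defendant = defendant_e)
      n_per_role <- sample(seq(params$utterances_per_role[1],
                               params$utterances_per_role[2]), 3, replace = TRUE)
      names(n_per_role) <- ROLES
      roles <- sample(rep(ROLES, times = n_per_role))
      n_utt <- length(roles)
      durs <- runif(n_utt, params$utterance_duration_s[1], params$utterance_duration_s[2])
      gaps <- runif(n_utt, params$inter_utterance_gap_s[1], params$inter_utterance_gap_s[2])
      # leading silence, then utterance/gap alternation
      starts <- 0.25 + cumsum(c(0, durs[-n_utt] + gaps[-n_utt]))
      ends <- starts + durs
      # court emotion: plurality over non-defendant utterances, ties broken
      # by the fixed emotion order
      nd <- role_emotion[roles[roles != "defendant"]]
      cnt <- table(factor(nd, levels = EMOTIONS))
      court_e <- EMOTIONS[which.max(cnt)]
      logic <- if (runif(1) < params$logic_given_court_emotion[[court_e]]) {
        "logical"
      } else {
        "non-logical"
      }
      ann <- t(vapply(roles, function(ro) {
        draw_annotators(role_emotion[[ro]], params$annotator_error_rate)
      }, character(3)))
      synth_seeds <- sample.int(.Machine$integer.max, n_utt)
      wavs <- if (audio) {
        lapply(seq_len(n_utt), function(i) {
          synthesize_utterance(role_emotion[[roles[i]]], roles[i], durs[i],
                               params, seed = synth_seeds[i])
        })
      } else {
        NULL
      }
      utt <- tibble::tibble(
        record_id = r,
        utterance_id = sprintf("r%03d_u%02d", r, seq_len(n_utt)),
        role = roles,
        start_s = starts,
        end_s = ends,
        duration_s = durs,
        true_emotion = unname(role_emotion[roles]),
        annotator_1 = ann[, 1],
        annotator_2 = ann[, 2],
        annotator_3 = ann[, 3]
      )
      if (audio) utt$waveform <- wavs
      utt_rows[[r]] <- utt
      rec_rows[[r]] <- tibble::tibble(
        record_id = r,
        judge_emotion = judge_e,
        plaintiff_emotion = plaintiff_e,
        defendant_emotion = defendant_e,
        court_emotion = court_e,
        logic_flag = logic,
        n_utterances = n_utt
      )
    }
    structure(
      list(utterances = dplyr::bind_rows(utt_rows),
           records = dplyr::bind_rows(rec_rows),
           params = params),
      class = "court_corpus"
    )
  })
}

#' @export
print.court_corpus <- function(x, ...) {
  cat(sprintf("<court_corpus> %d records, %d utterances%s\n",
              nrow(x$records), nrow(x$utterances),
              if ("waveform" %in% names(x$utterances)) " (with audio)" else ""))
  print(head(x$records))
  invisible(x)
}

#' Assemble the session waveform of one record
#'
#' Places each utterance of the record at its metadata position on a single
#' session timeline, with silence in the gaps, reproducing the kind of
#' continuous hearing recording that silence-based segmentation consumes.
#'
#' @param corpus A `court_corpus` generated with `audio = TRUE`.
#' @param record_id Which record to assemble.
#' @return A list with `waveform` (the session audio) and `roles` (tibble of
#'   role intervals: `record_id`, `role`, `start_s`, `end_s`).
#' @export
assemble_session <- function(corpus, record_id) {
  stopifnot(inherits(corpus, "court_corpus"))
  utt <- dplyr::filter(corpus$utterances, .data$record_id == !!record_id)
  if (nrow(utt) == 0) abort(sprintf("no record with id %s", record_id))
  if (!"waveform" %in% names(utt)) abort("corpus was generated without audio")
  sr <- corpus$params$sample_rate
  total_n <- as.integer(round((max(utt$end_s) + 0.25) * sr))
  session <- numeric(total_n)
  for (i in seq_len(nrow(utt))) {
    s <- utt$waveform[[i]]$samples
    at <- as.integer(round(utt$start_s[i] * sr))
    session[at + seq_along(s)] <- s
  }
  list(
    waveform = waveform(session, sr),
    roles = dplyr::select(utt, "record_id", "role", "start_s", "end_s")
  )
}

#' Write a corpus to disk as WAV files plus metadata tables
#'
#' Writes one 16-bit PCM mono WAV per utterance, an utterance metadata CSV
#' (`utterances.csv` with record id, role, boundaries, true emotion, the
#' three annotator labels and the record logic flag), a record-level table
#' (`records.csv`), and the generator parameters as JSON (`params.json`,
#' when the jsonlite package is available).
#'
#' @param corpus A `court_corpus` generated with `audio = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "court_corpus"))
  if (!"waveform" %in% names(corpus$utterances)) {
    abort("corpus was generated without audio")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utt <- corpus$utterances
  for (i in seq_len(nrow(utt))) {
    w <- utt$waveform[[i]]
    write_wav(w$samples, w$sample_rate,
              file.path(dir, paste0(utt$utterance_id[i], ".wav")))
  }
  meta <- dplyr::left_join(
    dplyr::select(utt, -"waveform"),
    dplyr::select(corpus$records, "record_id", "logic_flag"),
    by = "record_id"
  )
  write.csv(meta, file.path(dir, "utterances.csv"), row.names = FALSE)
  write.csv(corpus$records, file.path(dir, "records.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    pj <- corpus$params
    pj$acoustic_profile <- lapply(pj$acoustic_profile, unlist)
    jsonlite::write_json(pj, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}
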