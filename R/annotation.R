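#' Consensus of three expert labels
#'
#' The conventional 2-of-3 rule: if at least two of the three annotators
#' agree, their label is the consensus; if all three differ the utterance is
#' `"unresolved"` (and is excluded from training corpora downstream).
#' The result is invariant to the order of the three labels.
#'
#' @param labels Character vector of exactly 3 emotion labels.
#' @return A single emotion label, or `"unresolved"`.
#' @examples
#' consensus_label(c("angry", "angry", "fear"))   # "angry"
#' consensus_label(c("angry", "neutral", "fear")) # "unresolved"
#' @export
consensus_label <- function(labels) {
  if (length(labels) != 3) abort("exactly 3 annotator labels are required")
  if (!all(labels %in% EMOTIONS)) abort("labels outside the emotion vocabulary")
  cnt <- table(labels)
  if (max(cnt) >= 2) names(cnt)[which.max(cnt)] else "unresolved"
}

#' Add a consensus column to an annotated utterance table
#'
#' Applies [consensus_label()] row-wise over the `annotator_1..3` columns and
#' reports how many utterances were unresolved.
#'
#' @param data Tibble with columns `annotator_1`, `annotator_2`, `annotator_3`.
#' @param quiet Suppress the unresolved-count message?
#' @return `data` with a `consensus` column appended.
#' @export
add_consensus <- function(data, quiet = FALSE) {
  stopifnot(is.data.frame(data))
  cols <- paste0("annotator_", 1:3)
  if (!all(cols %in% names(data))) {
    abort("`data` needs columns annotator_1, annotator_2, annotator_3")
  }
  data$consensus <- vapply(seq_len(nrow(data)), function(i) {
    consensus_label(c(data$annotator_1[i], data$annotator_2[i], data$annotator_3[i]))
  }, character(1))
  n_unres <- sum(data$consensus == "unresolved")
  if (!quiet && n_unres > 0) {
    message(sprintf("%d of %d utterances unresolved (all three annotators disagree)",
                    n_unres, nrow(data)))
  }
  data
}

#' Split a corpus into an annotated training pool and a prediction pool
#'
#' Mirrors the study design: a fixed fraction of records (by default 10 of
#' 50) supplies expert consensus labels for training; the remaining records
#' are prediction-only. The split is by record, never by utterance, and is
#' deterministic given the seed.
#'
#' @param corpus A `court_corpus`.
#' @param n_train_records Number of records in the training pool (default 10).
#' @param seed Seed for the record split.
#' @return List with `train` (utterance tibble with a `consensus` column,
#'   unresolved utterances removed) and `predict` (the remaining utterances).
#' @export
training_split <- function(corpus, n_train_records = 10L, seed = 1L) {
  stopifnot(inherits(corpus, "court_corpus"))
  ids <- unique(corpus$utterances$record_id)
  if (n_train_records >= length(ids)) abort("`n_train_records` must leave records to predict")
  train_ids <- withr::with_seed(as.integer(seed), sample(ids, n_train_records))
  train <- add_consensus(
    dplyr::filter(corpus$utterances, .data$record_id %in% train_ids),
    quiet = TRUE
  )
  train <- dplyr::filter(train, .data$consensus != "unresolved")
  list(
    train = train,
    predict = dplyr::filter(corpus$utterances, !.data$record_id %in% train_ids)
  )
}
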