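#' Contingency table of record-level labels
#'
#' A thin typed wrapper around a counts matrix: conditioning levels as rows,
#' response levels as columns. The grand total always equals the number of
#' contributing records.
#'
#' @param counts Non-negative integer matrix with dimnames.
#' @param conditioning Name of the conditioning variable (rows).
#' @param response Name of the response variable (columns).
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(counts, conditioning = "conditioning",
                              response = "response") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry row and column level names")
  }
  structure(list(counts = counts, conditioning = conditioning,
                 response = response),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s (rows) x %s (columns), n = %d\n",
              x$conditioning, x$response, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.contingency_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE,
                                        responseName = "n")) |>
    stats::setNames(c(x$conditioning, x$response, "n"))
}

#' Record-level emotion from utterance predictions
#'
#' Aggregates the utterance predictions of one role within one record to a
#' single label: the plurality of the argmax labels; ties are broken by the
#' larger summed posterior mass of the tied labels, then by the fixed
#' emotion order (angry < neutral < fear).
#'
#' @param predictions Tibble of one role's utterances in one record with a
#'   `pred_emotion` column and optionally `p_angry`, `p_neutral`, `p_fear`.
#' @return A single emotion label.
#' @export
record_role_emotion <- function(predictions) {
  if (nrow(predictions) == 0) abort("no utterance predictions supplied")
  labs <- predictions$pred_emotion
  cnt <- table(factor(labs, levels = EMOTIONS))
  top <- EMOTIONS[cnt == max(cnt)]
  if (length(top) > 1 && all(c("p_angry", "p_neutral", "p_fear") %in% names(predictions))) {
    mass <- vapply(top, function(e) sum(predictions[[paste0("p_", e)]]),
                   numeric(1))
    names(mass) <- top
    top <- top[mass == max(mass)]
  }
  top[1]    # EMOTIONS order is preserved by table(); first tied level wins
}

#' Aggregate utterance predictions to record-level role emotions
#'
#' Applies [record_role_emotion()] per record and role, and derives the
#' courtroom ("court") emotion as the plurality label over all non-defendant
#' utterances of the record, with the same tie-break rule.
#'
#' @param predictions Utterance tibble with `record_id`, `role`,
#'   `pred_emotion` (and optionally the posterior columns).
#' @return A tibble with one row per record: `record_id`, `judge_emotion`,
#'   `plaintiff_emotion`, `defendant_emotion`, `court_emotion` (NA when a
#'   role has no utterances in a record).
#' @export
aggregate_record_emotions <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  need <- c("record_id", "role", "pred_emotion")
  if (!all(need %in% names(predictions))) {
    abort("`predictions` needs columns record_id, role, pred_emotion")
  }
  one_record <- function(df) {
    per_role <- vapply(ROLES, function(ro) {
      sub <- df[df$role == ro, , drop = FALSE]
      if (nrow(sub) == 0) NA_character_ else record_role_emotion(sub)
    }, character(1))
    nd <- df[df$role != "defendant", , drop = FALSE]
    court <- if (nrow(nd) == 0) NA_character_ else record_role_emotion(nd)
    tibble::tibble(
      judge_emotion = per_role[["judge"]],
      plaintiff_emotion = per_role[["plaintiff"]],
      defendant_emotion = per_role[["defendant"]],
      court_emotion = court
    )
  }
  predictions |>
    dplyr::group_by(.data$record_id) |>
    dplyr::group_modify(~ one_record(.x)) |>
    dplyr::ungroup()
}

#' Cross-tabulate record-level labels
#'
#' Builds the counts matrix behind the influence analysis: rows are the
#' conditioning role's emotion (or the pooled court emotion), columns the
#' defendant's emotion or logic flag. Records missing a required label are
#' excluded with a message reporting the count.
#'
#' @param records Record-level tibble with columns `judge_emotion`,
#'   `plaintiff_emotion`, `court_emotion`, `defendant_emotion`, `logic_flag`
#'   as applicable.
#' @param conditioning `"judge"`, `"plaintiff"` or `"court"`.
#' @param response `"defendant_emotion"` or `"logic"`.
#' @param quiet Suppress the exclusion message?
#' @return A [contingency_table()].
#' @examples
#' recs <- tibble::tibble(
#'   judge_emotion = c("angry", "angry", "neutral"),
#'   defendant_emotion = c("fear", "fear", "neutral")
#' )
#' cross_tabulate(recs, "judge", "defendant_emotion")$counts
#' @export
cross_tabulate <- function(records, conditioning = c("judge", "plaintiff", "court"),
                           response = c("defendant_emotion", "logic"),
                           quiet = FALSE) {
  conditioning <- match.arg(conditioning)
  response <- match.arg(response)
  cond_col <- paste0(conditioning, "_emotion")
  resp_col <- if (response == "logic") "logic_flag" else "defendant_emotion"
  for (cl in c(cond_col, resp_col)) {
    if (!cl %in% names(records)) abort(sprintf("`records` is missing column %s", cl))
  }
  cond_levels <- if (conditioning == "judge") c("angry", "neutral") else EMOTIONS
  resp_levels <- if (response == "logic") LOGIC_LEVELS else EMOTIONS
  ok <- !is.na(records[[cond_col]]) & !is.na(records[[resp_col]])
  if (!quiet && any(!ok)) {
    message(sprintf("%d record(s) missing a %s or %s label were excluded",
                    sum(!ok), conditioning, response))
  }
  if (any(!records[[cond_col]][ok] %in% cond_levels)) {
    # a judge predicted as fearful falls outside the two-level judge rows;
    # widen to the full vocabulary rather than silently drop records
    cond_levels <- EMOTIONS
  }
  cond <- factor(records[[cond_col]][ok], levels = cond_levels)
  resp <- factor(records[[resp_col]][ok], levels = resp_levels)
  counts <- table(cond, resp)
  m <- matrix(as.integer(counts), nrow = length(cond_levels),
              dimnames = list(cond_levels, resp_levels))
  contingency_table(m, conditioning = conditioning, response = response)
}

#' Chi-square and odds-ratio association statistics
#'
#' Pearson chi-square on the counts matrix (textbook expected-count formula,
#' no continuity correction) with `(r-1)(c-1)` degrees of freedom, plus the
#' odds ratio `ad/(bc)` of every cell-versus-rest 2x2 collapse. When any
#' expected count is below 5 the `small_cell_flag` is set and Fisher's exact
#' p-value is reported for each collapse.
#'
#' @param x A [contingency_table()] (or bare counts matrix).
#' @return An object of class `association_result` with fields `chi_square`,
#'   `degrees_of_freedom`, `p_value`, `odds_ratios` (tibble), and
#'   `small_cell_flag`.
#' @examples
#' tab <- contingency_table(matrix(c(10, 3, 2, 15), 2,
#'   dimnames = list(c("a", "b"), c("x", "y"))))
#' association_stats(tab)$odds_ratios
#' @export
association_stats <- function(x) {
  counts <- if (inherits(x, "contingency_table")) x$counts else as.matrix(x)
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("need at least a 2x2 table")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0)) {
    abort(sprintf("conditioning level '%s' has zero records",
                  rownames(counts)[which(rs == 0)[1]]))
  }
  if (any(cs == 0)) {
    abort(sprintf("response level '%s' has zero records",
                  colnames(counts)[which(cs == 0)[1]]))
  }
  expected <- outer(rs, cs) / n
  chi2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  small <- any(expected < 5)
  grid <- expand.grid(row = rownames(counts), col = colnames(counts),
                      stringsAsFactors = FALSE)
  ors <- purrr::pmap_dfr(grid, function(row, col) {
    a <- counts[row, col]
    b <- rs[row] - a
    cc <- cs[col] - a
    d <- n - a - b - cc
    m2 <- matrix(c(a, cc, b, d), 2)
    tibble::tibble(
      level = row, versus = col,
      odds_ratio = unname((a * d) / (b * cc)),
      fisher_p = if (small) fisher.test(m2)$p.value else NA_real_
    )
  })
  structure(list(
    chi_square = chi2, degrees_of_freedom = df,
    p_value = pchisq(chi2, df, lower.tail = FALSE),
    odds_ratios = ors, small_cell_flag = small, expected = expected
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g%s\n",
              x$chi_square, x$degrees_of_freedom, x$p_value,
              if (x$small_cell_flag) " (small expected cells: see Fisher p)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.association_result <- function(x, ...) x$odds_ratios

#' @exportS3Method generics::glance
glance.association_result <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square,
                 degrees_of_freedom = x$degrees_of_freedom,
                 p_value = x$p_value,
                 small_cell_flag = x$small_cell_flag)
}

drop_zero_rows <- function(tab, quiet = FALSE) {
  rs <- rowSums(tab$counts)
  if (any(rs == 0)) {
    if (!quiet) {
      message(sprintf("dropping empty %s level(s): %s", tab$conditioning,
                      paste(rownames(tab$counts)[rs == 0], collapse = ", ")))
    }
    tab$counts <- tab$counts[rs > 0, , drop = FALSE]
  }
  tab
}

row_conditionals <- function(counts) {
  sweep(counts, 1, pmax(rowSums(counts), 1), `/`)
}

#' Full influence report over a set of analyzed records
#'
#' Produces the three cross-tabulations at the heart of the analysis -
#' judge emotion vs defendant emotion, plaintiff emotion vs defendant
#' emotion, and pooled court emotion vs defendant logic - together with
#' association statistics and per-level conditional response distributions.
#' Conditioning levels with zero records are dropped (with a message) before
#' the statistics. When the generating parameters are supplied, the report
#' adds the planted vs recovered conditional matrices and their maximum
#' absolute deviation.
#'
#' @param records Record-level tibble (see [aggregate_record_emotions()];
#'   must also carry `logic_flag`).
#' @param planted Optional [court_params()] whose `defendant_given_judge`
#'   matrix is compared with the recovered conditionals.
#' @param quiet Suppress exclusion/drop messages?
#' @return An object of class `influence_report`: list with `tables`,
#'   `stats`, `conditionals`, `n_records` and (optionally) `recovery`.
#' @export
influence_report <- function(records, planted = NULL, quiet = FALSE) {
  specs <- list(
    judge = list(conditioning = "judge", response = "defendant_emotion"),
    plaintiff = list(conditioning = "plaintiff", response = "defendant_emotion"),
    court = list(conditioning = "court", response = "logic")
  )
  tables <- lapply(specs, function(sp) {
    drop_zero_rows(
      cross_tabulate(records, sp$conditioning, sp$response, quiet = quiet),
      quiet = quiet
    )
  })
  stats <- lapply(tables, association_stats)
  conditionals <- lapply(tables, function(tb) row_conditionals(tb$counts))
  out <- list(tables = tables, stats = stats, conditionals = conditionals,
              n_records = nrow(records))
  if (!is.null(planted)) {
    rec <- conditionals$judge[rownames(planted$defendant_given_judge), , drop = FALSE]
    dev <- abs(rec - planted$defendant_given_judge)
    out$recovery <- list(
      planted = planted$defendant_given_judge,
      recovered = rec,
      max_abs_deviation = max(dev)
    )
  }
  structure(out, class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("<influence_report> %d records\n\n", x$n_records))
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    cat(sprintf("-- %s -> %s\n", tb$conditioning, tb$response))
    print(tb$counts)
    print(x$stats[[nm]])
    cat("\n")
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("recovery: max |recovered - planted| = %.4f\n",
                x$recovery$max_abs_deviation))
  }
  invisible(x)
}

#' The published 50-record cross-tabulations
#'
#' Loads the three cross-tabulations reported for the original 50 court
#' hearing recordings (judge emotion vs defendant emotion, plaintiff emotion
#' vs defendant emotion, and courtroom emotion vs defendant logic), shipped
#' as a plain-text table with the package. The logic table is stored in the
#' same orientation as the others: conditioning emotion as rows.
#'
#' @return Named list of three [contingency_table()] objects:
#'   `judge`, `plaintiff`, `logic`.
#' @examples
#' sapply(court_tables(), function(t) sum(t$counts)) # 50 50 50
#' @export
court_tables <- function() {
  path <- system.file("extdata", "published_court_tables.csv",
                      package = "courttone", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  build <- function(tab_name, response) {
    d <- raw[raw$table == tab_name, ]
    rows <- unique(d$conditioning_level)
    cols <- unique(d$response_level)
    m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
    m[cbind(d$conditioning_level, d$response_level)] <- as.integer(d$count)
    contingency_table(m, conditioning = unique(d$conditioning),
                      response = response)
  }
  list(
    judge = build("judge_defendant", "defendant_emotion"),
    plaintiff = build("plaintiff_defendant", "defendant_emotion"),
    logic = build("court_logic", "logic")
  )
}
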