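test_that("record-level aggregation follows plurality with the documented tie-breaks", {
  # plain plurality
  d <- tibble::tibble(pred_emotion = c("fear", "fear", "angry"))
  expect_equal(record_role_emotion(d), "fear")
  expect_equal(record_role_emotion(tibble::tibble(pred_emotion = "neutral")),
               "neutral")
  # tie broken by summed posterior mass
  d2 <- tibble::tibble(
    pred_emotion = c("angry", "fear"),
    p_angry = c(0.7, 0.6), p_neutral = c(0.1, 0.0), p_fear = c(0.2, 0.4)
  )
  # summed mass: angry 1.3 vs fear 0.6 -> angry
  expect_equal(record_role_emotion(d2), "angry")
  # tie with no posteriors: fixed label order angry < neutral < fear
  d3 <- tibble::tibble(pred_emotion = c("neutral", "fear"))
  expect_equal(record_role_emotion(d3), "neutral")
  expect_error(record_role_emotion(d3[0, ]), "no utterance")
})

test_that("aggregation across records produces per-role and court emotions", {
  pred <- tibble::tibble(
    record_id = c(1, 1, 1, 1, 2, 2, 2),
    role = c("judge", "plaintiff", "defendant", "defendant",
             "judge", "judge", "defendant"),
    pred_emotion = c("angry", "neutral", "fear", "fear",
                     "neutral", "neutral", "angry")
  )
  out <- aggregate_record_emotions(pred)
  expect_equal(out$judge_emotion, c("angry", "neutral"))
  expect_equal(out$defendant_emotion, c("fear", "angry"))
  expect_true(is.na(out$plaintiff_emotion[2]))
  # court emotion pools judge + plaintiff utterances
  expect_equal(out$court_emotion, c("angry", "neutral"))
})

test_that("cross-tabulation matches a hand tally and conserves the record count", {
  recs <- tibble::tibble(
    judge_emotion = c("angry", "angry", "neutral", "neutral"),
    defendant_emotion = c("fear", "fear", "neutral", "angry"),
    court_emotion = c("angry", "angry", "neutral", "fear"),
    logic_flag = c("non-logical", "logical", "logical", "logical")
  )
  tab <- cross_tabulate(recs, "judge", "defendant_emotion")
  expect_equal(tab$counts["angry", "fear"], 2L)
  expect_equal(tab$counts["neutral", "neutral"], 1L)
  expect_equal(tab$counts["neutral", "angry"], 1L)
  expect_equal(sum(tab$counts), 4L)
  tl <- cross_tabulate(recs, "court", "logic")
  expect_equal(sum(tl$counts), 4L)
  expect_equal(tl$counts["angry", "logical"], 1L)
  # empty input gives an all-zero table
  expect_equal(sum(cross_tabulate(recs[0, ], "judge", "defendant_emotion")$counts), 0L)
  # rows missing a label are excluded with a message
  recs2 <- recs
  recs2$defendant_emotion[1] <- NA
  expect_message(t2 <- cross_tabulate(recs2, "judge", "defendant_emotion"),
                 "excluded")
  expect_equal(sum(t2$counts), 3L)
})

test_that("chi-square matches the independent implementation and classic identities", {
  # independence: counts proportional to the product of margins
  ind <- matrix(c(10, 20, 20, 40, 10, 20), 2,
                dimnames = list(c("a", "b"), c("x", "y", "z")))
  res <- association_stats(ind)
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_true(all(abs(res$odds_ratios$odds_ratio - 1) < 1e-12))
  # cross-check against stats::chisq.test on a random-ish table
  m <- matrix(c(12, 5, 9, 14, 7, 3), 2,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  res2 <- association_stats(m)
  ref <- suppressWarnings(chisq.test(m, correct = FALSE))
  expect_equal(res2$chi_square, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res2$degrees_of_freedom, unname(ref$parameter))
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-9)
  # 2x2 odds ratio ad/(bc); expected counts all >= 5 so no exact test
  m2 <- matrix(c(10, 3, 2, 15), 2, dimnames = list(c("a", "b"), c("x", "y")))
  r2 <- association_stats(m2)
  expect_equal(r2$odds_ratios$odds_ratio[r2$odds_ratios$level == "a" &
                                           r2$odds_ratios$versus == "x"], 25)
  expect_false(r2$small_cell_flag)
  expect_true(all(is.na(r2$odds_ratios$fisher_p)))
  # sparse table triggers the small-cell flag and Fisher exact p-values
  m3 <- matrix(c(5, 1, 1, 8), 2, dimnames = list(c("a", "b"), c("x", "y")))
  r3 <- association_stats(m3)
  expect_true(r3$small_cell_flag)
  expect_true(all(!is.na(r3$odds_ratios$fisher_p)))
  expect_equal(r3$odds_ratios$odds_ratio[r3$odds_ratios$level == "a" &
                                           r3$odds_ratios$versus == "x"], 40)
  expect_equal(r3$odds_ratios$fisher_p[1], fisher.test(m3)$p.value,
               tolerance = 1e-9)
  # degenerate levels error by name
  z <- matrix(c(0, 5, 0, 7), 2, dimnames = list(c("dead", "alive"), c("x", "y")))
  expect_error(association_stats(z), "dead")
})

test_that("chi-square is invariant under row and column permutation", {
  m <- matrix(c(10, 1, 10, 8, 19, 2), 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("c1", "c2", "c3")))
  base <- association_stats(m)$chi_square
  expect_equal(association_stats(m[2:1, ])$chi_square, base, tolerance = 1e-12)
  expect_equal(association_stats(m[, c(3, 1, 2)])$chi_square, base,
               tolerance = 1e-12)
})

test_that("the influence report assembles tables, stats and recovery diagnostics", {
  p <- court_params(n_records = 300, seed = 44)
  corp <- sample_corpus(p, audio = FALSE)
  rep <- influence_report(corp$records, planted = p, quiet = TRUE)
  expect_named(rep$tables, c("judge", "plaintiff", "court"))
  for (tb in rep$tables) expect_equal(sum(tb$counts), 300)
  expect_true(all(abs(rowSums(rep$conditionals$judge) - 1) < 1e-9))
  expect_lt(rep$recovery$max_abs_deviation, 0.1)
  expect_s3_class(rep$stats$judge, "association_result")
  expect_output(print(rep), "judge -> defendant_emotion")
})

test_that("independence tests hold their nominal size and detect planted dependence", {
  unif <- matrix(1 / 3, 2, 3, dimnames = list(c("angry", "neutral"), EMOTIONS))
  rejections_null <- 0
  for (s in 1:20) {
    p <- court_params(n_records = 200, defendant_given_judge = unif,
                      seed = 100 + s)
    corp <- sample_corpus(p, audio = FALSE)
    tab <- cross_tabulate(corp$records, "judge", "defendant_emotion", quiet = TRUE)
    pv <- association_stats(tab)$p_value
    if (pv < 0.05) rejections_null <- rejections_null + 1
  }
  expect_lte(rejections_null, 4)       # binomial band around the 5% size
  rejections_dep <- 0
  for (s in 1:20) {
    p <- court_params(n_records = 500, seed = 200 + s)  # published-strength rows
    corp <- sample_corpus(p, audio = FALSE)
    tab <- cross_tabulate(corp$records, "judge", "defendant_emotion", quiet = TRUE)
    if (association_stats(tab)$p_value < 0.05) rejections_dep <- rejections_dep + 1
  }
  expect_gte(rejections_dep / 20, 0.95)
})

test_that("tidy methods return long tables", {
  tabs <- court_tables()
  td <- generics::tidy(tabs$judge)
  expect_named(td, c("judge", "defendant_emotion", "n"))
  expect_equal(sum(td$n), 50)
  ar <- association_stats(tabs$judge)
  expect_named(generics::glance(ar),
               c("chi_square", "degrees_of_freedom", "p_value", "small_cell_flag"))
})
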