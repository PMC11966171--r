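test_that("response normalization applies the canonical-text rule", {
  expect_equal(normalize_response("The  Jacket, hung!"), "the jacket hung")
  expect_equal(normalize_response("the jacket hung"), "the jacket hung")
  expect_equal(normalize_response("Drop the two…"), "drop the two")
  expect_equal(normalize_response(""), "")
  # idempotent on anything
  raw <- c("A-B c!", " x  y ", "Mixed CASE 12")
  expect_equal(normalize_response(normalize_response(raw)),
               normalize_response(raw))
})

test_that("digit matching counts positional errors from 0/6 to 6/6", {
  expect_equal(digit_match("123456", "123456"), 0L)
  expect_equal(digit_match("123456", "123455"), 1L)
  expect_equal(digit_match("123456", "654321"), 6L)
  expect_equal(digit_match("123456", "123"), 3L)
  expect_equal(digit_match("123456", ""), 6L)
  expect_error(digit_match("12345", "123456"), "6 digits")
  expect_error(digit_match("123456", "12a456"), "non-digit")
  # errors + correct digits conserve 6
  set.seed(41)
  for (i in 1:20) {
    tgt <- paste(sample(1:9, 6, replace = TRUE), collapse = "")
    rsp <- paste(sample(1:9, 6, replace = TRUE), collapse = "")
    e <- digit_match(tgt, rsp)
    correct <- sum(strsplit(tgt, "")[[1]] == strsplit(rsp, "")[[1]])
    expect_equal(e + correct, 6)
  }
})

test_that("string metrics are zero on identical inputs", {
  s <- "the air is pure"
  expect_equal(wer(s, s), 0)
  expect_equal(levenshtein_norm(s, s), 0)
  expect_equal(jaro_distance(s, s), 0)
  expect_equal(dtw_sequence_distance("123456", "123456"), 0)
})

test_that("metric spot values match hand-computed expectations", {
  expect_equal(wer("an abrupt start does not win the prize",
                   "an abrupt start does not win a prize"), 1 / 8)
  expect_equal(wer("an abrupt start does not win the prize", ""), 1)
  expect_error(wer("", "x"), "non-empty")
  expect_equal(levenshtein_norm("kitten", "sitting"), 3 / 6)
  expect_equal(levenshtein_norm("a", "b"), 1)
  expect_equal(jaro_distance("martha", "marhta"), 1 - 0.9444444,
               tolerance = 1e-6)
  expect_equal(jaro_distance("abc", "xyz"), 1)
})

test_that("string metrics agree with independent oracles exhaustively", {
  # every ordered pair of strings up to length 3 over a 3-symbol alphabet
  strs <- all_strings(c("a", "b", "c"), 3)
  for (s1 in strs) {
    for (s2 in strs) {
      expect_equal(levenshtein_norm(s1, s2),
                   oracle_levenshtein(s1, s2) / nchar(s1))
      expect_equal(jaro_distance(s1, s2), oracle_jaro(s1, s2),
                   tolerance = 1e-12)
      expect_equal(dtw_sequence_distance(s1, s2), oracle_dtw(s1, s2),
                   tolerance = 1e-12)
    }
  }
})

test_that("string metrics agree with oracles on sampled longer pairs", {
  set.seed(42)
  alphabet <- c("a", "b", "c")
  for (i in 1:2000) {
    s1 <- random_string(alphabet, sample(1:8, 1))
    s2 <- random_string(alphabet, sample(1:8, 1))
    expect_equal(levenshtein_norm(s1, s2),
                 oracle_levenshtein(s1, s2) / nchar(s1))
    expect_equal(jaro_distance(s1, s2), oracle_jaro(s1, s2),
                 tolerance = 1e-12)
  }
  # DTW brute force is exponential; sample shorter pairs
  for (i in 1:300) {
    s1 <- random_string(alphabet, sample(1:6, 1))
    s2 <- random_string(alphabet, sample(1:6, 1))
    expect_equal(dtw_sequence_distance(s1, s2), oracle_dtw(s1, s2),
                 tolerance = 1e-12)
  }
})

test_that("word-level WER agrees with an adist-based oracle", {
  set.seed(43)
  vocab <- c("the", "cat", "sat", "mat", "dog", "ran", "big", "red")
  for (i in 1:300) {
    t_words <- sample(vocab, sample(3:8, 1), replace = TRUE)
    r_words <- sample(vocab, sample(0:8, 1), replace = TRUE)
    got <- wer(paste(t_words, collapse = " "), paste(r_words, collapse = " "))
    want <- min(1, oracle_word_edit(t_words, r_words) / length(t_words))
    expect_equal(got, want)
  }
})

test_that("DTW favours deletions over substitutions at equal length", {
  set.seed(44)
  for (i in 1:100) {
    tgt <- sample(1:9, 6, replace = TRUE)
    pos <- sample(6, 1)
    deletion <- tgt[-pos]
    substitution <- tgt
    substitution[pos] <- sample(setdiff(1:9, tgt[pos]), 1)
    d_del <- dtw_sequence_distance(as.character(tgt), as.character(deletion))
    d_sub <- dtw_sequence_distance(as.character(tgt),
                                   as.character(substitution))
    expect_lte(d_del, d_sub)
  }
})

test_that("DTW distance correlates with digit-match errors", {
  set.seed(45)
  n <- 400
  errors <- integer(n)
  dtw_d <- numeric(n)
  for (i in seq_len(n)) {
    tgt <- sample(1:9, 6, replace = TRUE)
    rsp <- tgt
    k <- sample(0:4, 1)
    if (k > 0) {
      flip <- sample(6, k)
      rsp[flip] <- vapply(rsp[flip],
                          function(d) sample(setdiff(1:9, d), 1), integer(1))
    }
    errors[i] <- digit_match(paste(tgt, collapse = ""),
                             paste(rsp, collapse = ""))
    dtw_d[i] <- dtw_sequence_distance(as.character(tgt), as.character(rsp))
  }
  expect_gt(stats::cor(errors, dtw_d), 0.7)
})

test_that("WER and normalized Levenshtein correlate over corruptions", {
  set.seed(46)
  texts <- sentence_texts()[1:40]
  w <- numeric(0)
  l <- numeric(0)
  for (t in texts) {
    words <- strsplit(t, " ")[[1]]
    for (k in 0:3) {
      keep <- if (k == 0) words else words[-sample(length(words),
                                                   min(k, length(words) - 1))]
      resp <- paste(keep, collapse = " ")
      w <- c(w, wer(t, resp))
      l <- c(l, levenshtein_norm(t, resp))
    }
  }
  expect_gt(stats::cor(w, l), 0.8)
})

test_that("RT adjustment subtracts stimulus duration", {
  expect_equal(adjust_rt(6.3, 3.6), 2.7)
  expect_equal(adjust_rt(3.6, 3.6), 0)
  expect_equal(adjust_rt(2.0, 3.6), -1.6)  # typing during playback
  expect_error(adjust_rt(-1, 3.6), "positive")
})

test_that("score_responses computes per-trial metrics for each experiment", {
  mat <- shared_material()
  m2 <- build_exp2_manifest(42, mat)[1:30, ]
  model <- listener_model()
  resp <- simulate_exp23_listeners(m2, model, n_subjects = 3, n_trials = 10,
                                   seed = 7)
  scored <- score_responses(resp, m2)
  expect_true(all(c("digit_errors", "dtw_distance", "rt_adj_s") %in%
                    names(scored)))
  expect_true(all(scored$digit_errors >= 0 & scored$digit_errors <= 6))
  expect_true(all(scored$dtw_distance >= 0))

  m3 <- build_exp3_manifest(42, mat)[1:24, ]
  resp3 <- simulate_exp23_listeners(m3, model, n_subjects = 3, n_trials = 8,
                                    seed = 8)
  scored3 <- score_responses(resp3, m3)
  expect_true(all(c("wer", "accuracy", "levenshtein", "jaro") %in%
                    names(scored3)))
  expect_true(all(scored3$wer >= 0 & scored3$wer <= 1))
  expect_equal(scored3$accuracy, 1 - scored3$wer)
  bad <- resp3
  bad$stimulus_id[1] <- "nonexistent"
  expect_error(score_responses(bad, m3), "missing from the manifest")
})
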