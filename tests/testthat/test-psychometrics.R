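make_scored_exp1 <- function(model, n_subjects = 20, n_trials = 150,
                             seed = 13) {
  m <- small_exp1_manifest()
  resp <- simulate_exp1_listeners(m, model, n_subjects = n_subjects,
                                  n_trials = n_trials, seed = seed)
  score_responses(resp, m)
}

test_that("the psychometric fit recovers a constructed threshold", {
  model <- listener_model(subject_sd = 0.2)
  scored <- make_scored_exp1(model)
  fit <- fit_psychometric(scored)
  expect_s3_class(fit, "psychometric_fit")
  th <- threshold50(fit, "tonal", 220, n_boot = 0)
  truth <- model_threshold50(listener_model(), "tonal", 220)
  expect_true(th$attained)
  expect_lt(abs(th$threshold50 - truth), 0.08)
})

test_that("the morph coefficient is positive when P(diphthong) rises", {
  scored <- make_scored_exp1(listener_model(subject_sd = 0))
  fit <- fit_psychometric(scored)
  co <- tidy(fit)
  expect_gt(co$estimate[co$term == "morph"], 0)
})

test_that("thresholds are flagged unattained on flat curves", {
  flat <- function(m) 0.5
  expect_true(is.na(roughspeech:::curve_threshold50(flat)))
  # logistic with midpoint 0.4: the halfway crossing solves
  # plogis(10 (m - 0.4)) = (P(0) + P(1)) / 2 in closed form
  p_fun <- function(m) stats::plogis(10 * (m - 0.4))
  expected <- 0.4 + stats::qlogis((p_fun(0) + p_fun(1)) / 2) / 10
  expect_equal(roughspeech:::curve_threshold50(p_fun), expected,
               tolerance = 1e-4)
  # fully symmetric curve: crossing exactly at the midpoint
  p_sym <- function(m) stats::plogis(10 * (m - 0.5))
  expect_equal(roughspeech:::curve_threshold50(p_sym), 0.5, tolerance = 1e-4)
})

test_that("threshold invariance under condition relabeling", {
  scored <- make_scored_exp1(listener_model(subject_sd = 0.1), seed = 14)
  fit <- fit_psychometric(scored)
  relabeled <- scored
  map <- c(tonal = "zz_tonal", am = "aa_am", subharmonics = "subharmonics",
           chaos = "chaos", whisper = "whisper")
  relabeled$condition <- unname(map[relabeled$condition])
  fit2 <- fit_psychometric(relabeled)
  t1 <- threshold50(fit, "tonal", 440, n_boot = 0)$threshold50
  t2 <- threshold50(fit2, "zz_tonal", 440, n_boot = 0)$threshold50
  expect_equal(t1, t2, tolerance = 1e-6)
})

test_that("bootstrap CIs bracket the threshold point estimate", {
  scored <- make_scored_exp1(listener_model(subject_sd = 0.2), seed = 15)
  fit <- fit_psychometric(scored)
  set.seed(1)
  th <- threshold50(fit, "am", 440, n_boot = 60)
  expect_true(th$attained)
  expect_lte(th$ci_lower, th$threshold50)
  expect_gte(th$ci_upper, th$threshold50)
})

test_that("condition contrasts are null on identical data", {
  scored <- make_scored_exp1(listener_model(subject_sd = 0.2), seed = 16)
  both <- rbind(
    transform(scored[scored$condition == "tonal", ], condition = "A"),
    transform(scored[scored$condition == "tonal", ], condition = "B")
  )
  set.seed(2)
  ct <- condition_contrast(both, "diphthong_response", "A", "B",
                           n_boot = 200)
  expect_equal(ct$difference, 0)
  expect_lte(ct$ci_lower, 0)
  expect_gte(ct$ci_upper, 0)
  single <- both[both$subject_id == both$subject_id[1], ]
  expect_error(condition_contrast(single, "diphthong_response", "A", "B"),
               "2 subjects")
})

test_that("condition contrasts detect a simulated accuracy deficit", {
  mat <- shared_material()
  m3 <- build_exp3_manifest(42, mat)
  exp3 <- listener_model()$exp3
  exp3$p_word_error[exp3$condition == "whisper_intermittent"] <-
    pmin(1, exp3$p_word_error[exp3$condition == "no_nlp"] + 0.3)
  model <- listener_model(exp3 = exp3, subject_sd = 0.1)
  resp <- simulate_exp23_listeners(m3, model, n_subjects = 12,
                                   n_trials = 80, seed = 17, noise = TRUE)
  scored <- score_responses(resp, m3)
  set.seed(3)
  ct <- condition_contrast(scored, "accuracy", "whisper_intermittent",
                           "no_nlp", n_boot = 400)
  expect_lt(ct$difference, -0.15)
  expect_lt(ct$ci_upper, 0)
})

test_that("tidy, glance and autoplot expose the fit in standard forms", {
  scored <- make_scored_exp1(listener_model(), n_subjects = 10,
                             n_trials = 80, seed = 18)
  fit <- fit_psychometric(scored)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_trials, nrow(scored))
  expect_equal(gl$n_subjects, 10)
  p <- autoplot(fit, pitch_hz = c(220, 880))
  expect_s3_class(p, "ggplot")
  pw <- autoplot(whisper_source(0.1, SR))
  expect_s3_class(pw, "ggplot")
  ps <- plot_spectrum(tone(440, 0.2))
  expect_s3_class(ps, "ggplot")
})

test_that("under-filled conditions are dropped with a warning", {
  scored <- make_scored_exp1(listener_model(), n_subjects = 6,
                             n_trials = 100, seed = 19)
  few <- scored[scored$condition != "am" | seq_len(nrow(scored)) %% 37 == 0, ]
  expect_warning(fit <- fit_psychometric(few, min_cell = 50), "skipped")
  expect_false("am" %in% fit$conditions)
})
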