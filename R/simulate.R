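#' A parametric synthetic-listener model
#'
#' Describes how simulated listeners respond to the three experiments. The
#' default parameters are illustrative: they qualitatively mirror the
#' reported response structure — vowel-discrimination thresholds that rise
#' with pitch fastest when no nonlinear phenomena are present, digit accuracy
#' that improves with SNR, and sentence accuracy that collapses under noise
#' for whisper / frequency-jump / mixed manipulations — but they are not
#' estimates of any real listener population.
#'
#' @param exp1 Tibble with one row per vowel-experiment condition: `condition`,
#'   `slope` (logit units per unit morph) and a midpoint linear in pitch,
#'   `midpoint_base` (midpoint at 110 Hz) plus `midpoint_rise` (midpoint
#'   increase per kHz of pitch). P(diphthong) is a lapse-mixed logistic in
#'   morph around that midpoint.
#' @param exp2 Tibble with one row per word-experiment condition: `condition`,
#'   `logit_err_base` (per-digit error log-odds at SNR 0, original pitch),
#'   plus scalars `snr_slope` (log-odds per dB) and `pitch_up` (added
#'   log-odds per octave of pitch shift).
#' @param exp3 Tibble with one row per sentence condition x noise arm:
#'   `condition`, `noise`, `p_word_error` (per-word deletion/substitution
#'   probability).
#' @param subject_sd Standard deviation of subject intercepts (logit scale).
#' @param lapse Lapse rate in \[0, 0.1\]: probability of a uniform guess.
#' @param snr_slope,pitch_up See `exp2`.
#' @return An object of class `listener_model`.
#' @export
#' @examples
#' listener_model()
listener_model <- function(exp1 = NULL, exp2 = NULL, exp3 = NULL,
                           subject_sd = 0.3, lapse = 0.02,
                           snr_slope = -0.18, pitch_up = 0.25) {
  if (lapse < 0 || lapse > 0.1) stop("lapse rate must lie in [0, 0.1]")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (is.null(exp1)) {
    exp1 <- tibble::tibble(
      condition = c("tonal", "am", "subharmonics", "chaos", "whisper"),
      slope = rep(9, 5),
      midpoint_base = rep(0.22, 5),
      midpoint_rise = c(0.75, 0.35, 0.32, 0.28, 0.25)
    )
  }
  if (is.null(exp2)) {
    exp2 <- tibble::tibble(
      condition = c("none", "frequency_jump", "am", "subharmonics",
                    "chaos", "whisper"),
      logit_err_base = c(-1.6, -1.3, -1.6, -1.6, -1.5, -1.4)
    )
  }
  if (is.null(exp3)) {
    conds <- c("original", "no_nlp", "frequency_jumps", "mixed",
               "whisper_continuous", "whisper_intermittent",
               "am_continuous", "am_intermittent",
               "subharmonics_continuous", "subharmonics_intermittent",
               "chaos_continuous", "chaos_intermittent")
    quiet <- c(0.05, 0.08, 0.10, 0.12, 0.09, 0.11,
               0.08, 0.08, 0.08, 0.08, 0.09, 0.09)
    noisy <- c(0.38, 0.45, 0.74, 0.79, 0.73, 0.84,
               0.45, 0.46, 0.51, 0.47, 0.59, 0.64)
    exp3 <- tibble::tibble(
      condition = rep(conds, 2),
      noise = rep(c(FALSE, TRUE), each = length(conds)),
      p_word_error = c(quiet, noisy)
    )
  }
  stopifnot(all(exp3$p_word_error >= 0 & exp3$p_word_error <= 1),
            all(exp1$slope > 0))
  structure(list(exp1 = exp1, exp2 = exp2, exp3 = exp3,
                 subject_sd = subject_sd, lapse = lapse,
                 snr_slope = snr_slope, pitch_up = pitch_up),
            class = "listener_model")
}

#' @export
print.listener_model <- function(x, ...) {
  cat(sprintf(
    "<listener_model: subject_sd %.2f, lapse %.2f; %d/%d/%d condition rows>\n",
    x$subject_sd, x$lapse, nrow(x$exp1), nrow(x$exp2), nrow(x$exp3)))
  invisible(x)
}

# Population P(diphthong) for one model cell, at subject intercept 0.
# Midpoint moves linearly with pitch; the lapse mixes in uniform guessing.
model_p_diphthong <- function(model, condition, pitch_hz, morph,
                              subject_intercept = 0) {
  row <- model$exp1[model$exp1$condition == condition, ]
  if (nrow(row) != 1L) stop("condition not in listener model: ", condition)
  mid <- row$midpoint_base + row$midpoint_rise * (pitch_hz - 110) / 1000
  p <- stats::plogis(row$slope * (morph - mid) + subject_intercept)
  model$lapse * 0.5 + (1 - model$lapse) * p
}

#' True 50% threshold implied by a listener model
#'
#' Computes, on the model's own population response curve, the morph value
#' where P(diphthong) crosses halfway between its values at morph 0 and
#' morph 1 — the same definition the estimator uses, so parameter-recovery
#' checks compare like with like.
#'
#' @param model A [listener_model()].
#' @param condition Vowel-experiment condition label.
#' @param pitch_hz Pitch in Hz.
#' @return Morph fraction in \[0, 1\], or `NA` if the curve never crosses.
#' @export
model_threshold50 <- function(model, condition, pitch_hz) {
  p_fun <- function(m) model_p_diphthong(model, condition, pitch_hz, m)
  curve_threshold50(p_fun)
}

#' Simulate listeners for the vowel-discrimination experiment
#'
#' Each simulated subject performs `n_trials` trials (200 in the original
#' design), one per randomly drawn prototype with a randomly chosen
#' condition row. Binary diphthong responses are drawn from the model's
#' logistic surface plus a per-subject intercept and a lapse rate.
#'
#' @param manifest Tibble from [build_exp1_manifest()].
#' @param model A [listener_model()].
#' @param n_subjects Number of subjects (>= 2).
#' @param n_trials Trials per subject (default 200).
#' @param seed Integer seed.
#' @return Tibble: `stimulus_id`, `subject_id`, `response` (0/1), `rt_s`.
#' @export
simulate_exp1_listeners <- function(manifest, model, n_subjects,
                                    n_trials = 200, seed = 1) {
  stopifnot(inherits(model, "listener_model"))
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (!all(manifest$experiment == 1L)) {
    stop("manifest must come from the vowel experiment")
  }
  protos <- split(seq_len(nrow(manifest)), manifest$prototype_id)
  with_seed(seed, {
    intercepts <- stats::rnorm(n_subjects, 0, model$subject_sd)
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      take_proto <- sample(names(protos),
                           min(n_trials, length(protos)))
      rows <- vapply(take_proto, function(p) {
        idx <- protos[[p]]
        idx[sample.int(length(idx), 1)]
      }, integer(1))
      trials <- manifest[rows, ]
      pars <- model$exp1[match(trials$condition, model$exp1$condition), ]
      if (anyNA(pars$slope)) stop("condition not in listener model")
      mid <- pars$midpoint_base +
        pars$midpoint_rise * (trials$f0_hz - 110) / 1000
      p_core <- stats::plogis(pars$slope * (trials$morph - mid) +
                                intercepts[s])
      p <- model$lapse * 0.5 + (1 - model$lapse) * p_core
      tibble::tibble(
        stimulus_id = trials$stimulus_id,
        subject_id = sprintf("s%03d", s),
        response = stats::rbinom(nrow(trials), 1, p),
        rt_s = stats::rlnorm(nrow(trials), log(1.5), 0.4)
      )
    })
  })
}

#' Simulate listeners for the word and sentence experiments
#'
#' Word experiment: each subject hears `n_trials` sequences (100 in the
#' original design); every digit is independently misheard with a
#' probability from the model's SNR-by-condition curve plus a subject
#' intercept, wrong digits drawn uniformly from the remaining eight.
#' Sentence experiment: every word is independently deleted or substituted
#' with the model's per-condition error probability (substitutions drawn
#' from the corpus vocabulary). Response times are lognormal latencies added
#' to the stimulus duration.
#'
#' @param manifest Tibble from [build_exp2_manifest()] or
#'   [build_exp3_manifest()].
#' @param model A [listener_model()].
#' @param n_subjects Number of subjects (>= 2).
#' @param n_trials Trials per subject (default 100 for words, 60 for
#'   sentences).
#' @param seed Integer seed.
#' @param noise Sentence experiment only: simulate the masking-noise arm
#'   (default `FALSE`).
#' @return Tibble: `stimulus_id`, `subject_id`, `response`, `rt_s`.
#' @export
simulate_exp23_listeners <- function(manifest, model, n_subjects,
                                     n_trials = NULL, seed = 1,
                                     noise = FALSE) {
  stopifnot(inherits(model, "listener_model"))
  if (n_subjects < 2) stop("need at least 2 subjects")
  exp_id <- unique(manifest$experiment)
  if (length(exp_id) != 1L || !exp_id %in% c(2L, 3L)) {
    stop("manifest must come from the word or sentence experiment")
  }
  if (is.null(n_trials)) n_trials <- if (exp_id == 2L) 100 else 60
  with_seed(seed, {
    intercepts <- stats::rnorm(n_subjects, 0, model$subject_sd)
    if (exp_id == 2L) {
      simulate_exp2_inner(manifest, model, n_subjects, n_trials, intercepts)
    } else {
      simulate_exp3_inner(manifest, model, n_subjects, n_trials, intercepts,
                          noise)
    }
  })
}

simulate_exp2_inner <- function(manifest, model, n_subjects, n_trials,
                                intercepts) {
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    trials <- manifest[sample.int(nrow(manifest),
                                  min(n_trials, nrow(manifest))), ]
    purrr::map_dfr(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      row <- model$exp2[model$exp2$condition == tr$condition, ]
      if (nrow(row) != 1L) stop("condition not in listener model: ",
                                tr$condition)
      lp <- row$logit_err_base + model$snr_slope * tr$snr_db +
        model$pitch_up * tr$pitch_shift_oct + intercepts[s]
      p_err <- model$lapse * 0.5 + (1 - model$lapse) * stats::plogis(lp)
      digs <- as.integer(strsplit(tr$digits, "")[[1]])
      heard <- vapply(digs, function(d) {
        if (stats::runif(1) < p_err) sample(setdiff(1:9, d), 1) else d
      }, integer(1))
      tibble::tibble(
        stimulus_id = tr$stimulus_id,
        subject_id = sprintf("s%03d", s),
        response = paste(heard, collapse = ""),
        rt_s = tr$duration_s + stats::rlnorm(1, log(2.7), 0.35)
      )
    })
  })
}

simulate_exp3_inner <- function(manifest, model, n_subjects, n_trials,
                                intercepts, noise) {
  vocab <- unique(unlist(strsplit(unique(manifest$text), " ")))
  err_tab <- model$exp3[model$exp3$noise == noise, ]
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    trials <- manifest[sample.int(nrow(manifest),
                                  min(n_trials, nrow(manifest))), ]
    purrr::map_dfr(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      row <- err_tab[err_tab$condition == tr$condition, ]
      if (nrow(row) != 1L) stop("condition not in listener model: ",
                                tr$condition)
      lp <- stats::qlogis(pmin(pmax(row$p_word_error, 1e-4), 1 - 1e-4)) +
        intercepts[s]
      p_err <- model$lapse * 0.5 + (1 - model$lapse) * stats::plogis(lp)
      words <- strsplit(normalize_response(tr$text), " ")[[1]]
      heard <- character(0)
      for (w in words) {
        if (stats::runif(1) < p_err) {
          if (stats::runif(1) < 0.5) next  # deletion
          heard <- c(heard, sample(vocab, 1))  # substitution
        } else {
          heard <- c(heard, w)
        }
      }
      tibble::tibble(
        stimulus_id = tr$stimulus_id,
        subject_id = sprintf("s%03d", s),
        response = paste(heard, collapse = " "),
        rt_s = tr$duration_s + stats::rlnorm(1, log(4), 0.4)
      )
    })
  })
}
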