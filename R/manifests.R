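# Stimulus manifests: one row per stimulus, every parameter explicit, pure
# functions of the seed. Rendering any row is a pure function of the row
# (plus the material store for experiments 2 and 3).

ROUGHSPEECH_SR <- 22050

exp1_conditions <- c("tonal", "am", "subharmonics", "chaos", "whisper")
exp2_conditions <- c("none", "frequency_jump", "am", "subharmonics",
                     "chaos", "whisper")
exp2_pitch_levels <- c("original", "up1", "up1.5")
exp3_conditions <- c("original", "no_nlp", "frequency_jumps", "mixed",
                     "whisper_continuous", "whisper_intermittent",
                     "am_continuous", "am_intermittent",
                     "subharmonics_continuous", "subharmonics_intermittent",
                     "chaos_continuous", "chaos_intermittent")

#' Stimulus manifest for the vowel-discrimination experiment
#'
#' Creates 999 prototypes — each 700 ms, with f0 drawn log-uniformly between
#' 110 Hz (A2) and 880 Hz (A5), a 50% chance of being a diphthong with morph
#' drawn from \{0.1, ..., 1.0\} — and crosses each with the five NLP
#' conditions (tonal, AM, subharmonics, chaos, whisper) for 4995 stimuli.
#' Per-prototype manipulation parameters are drawn from the stated ranges:
#' AM 50-150 Hz at depth 0.4-0.6, subharmonics at f0/2 with depth 0.4-0.6,
#' jitter of 2-4 semitones at 1 kHz. The manifest is byte-identical for a
#' given seed.
#'
#' @param seed Integer master seed.
#' @return A tibble with one row per stimulus (4995 rows).
#' @export
#' @examples
#' m <- build_exp1_manifest(1)
#' nrow(m)
build_exp1_manifest <- function(seed) {
  vowels <- c("a", "o", "e", "i", "u")
  with_seed(seed, {
    n_proto <- 999L
    f0 <- exp(stats::runif(n_proto, log(110), log(880)))
    is_diph <- stats::runif(n_proto) < 0.5
    morph <- ifelse(is_diph, sample.int(10, n_proto, replace = TRUE) / 10, 0)
    vowel_from <- sample(vowels, n_proto, replace = TRUE)
    vowel_to <- vapply(vowel_from, function(v) {
      sample(setdiff(vowels, v), 1)
    }, character(1))
    vowel_to[!is_diph] <- vowel_from[!is_diph]
    proto <- tibble::tibble(
      prototype_id = seq_len(n_proto),
      f0_hz = f0,
      morph = morph,
      vowel_from = vowel_from,
      vowel_to = vowel_to,
      am_freq_hz = stats::runif(n_proto, 50, 150),
      am_depth = stats::runif(n_proto, 0.4, 0.6),
      sub_ratio = 2L,
      sub_depth = stats::runif(n_proto, 0.4, 0.6),
      jitter_depth_st = stats::runif(n_proto, 2, 4),
      jitter_rate_hz = 1000
    )
    out <- tidyr::crossing(proto, condition = exp1_conditions) |>
      dplyr::arrange(.data$prototype_id,
                     match(.data$condition, exp1_conditions)) |>
      dplyr::mutate(
        experiment = 1L,
        stimulus_id = sprintf("e1_%04d_%s", .data$prototype_id,
                              .data$condition),
        duration_s = 0.7,
        rolloff_db_oct = 3,
        seed = purrr::map_int(dplyr::row_number(),
                              function(i) derive_seed(seed, i))
      ) |>
      dplyr::select("stimulus_id", "experiment", "prototype_id", "condition",
                    "f0_hz", "morph", "vowel_from", "vowel_to", "duration_s",
                    "rolloff_db_oct", "am_freq_hz", "am_depth", "sub_ratio",
                    "sub_depth", "jitter_depth_st", "jitter_rate_hz", "seed")
    out
  })
}

#' Stimulus manifest for the word-discrimination experiment
#'
#' Creates 1300 six-digit sequences (digits 1-9, zero excluded, all six from
#' one of the eight synthetic speakers), each in a condition drawn uniformly
#' from the 18-cell grid of six NLP conditions (none, frequency jump, AM,
#' subharmonics, chaos, whisper) crossed with three pitch levels (original,
#' +1 octave, +1.5 octaves; whispered stimuli carry no pitch shift), mixed
#' with masking noise at an SNR drawn uniformly from \[-6, 15\] dB.
#' Manipulation parameters follow the stated ranges: AM 50-150 Hz at depth
#' 0.3-0.6, subharmonics at f0/2 with depth 0.3-0.5, jitter 1-4 semitones;
#' per-digit jump points (25-75% of the token) and magnitudes (3-12 st) are
#' drawn at render time from the record seed.
#'
#' @param seed Integer master seed.
#' @param material A [make_material()] store; defaults to
#'   `make_material(seed)`. Pass the same material to [render_stimulus()].
#' @return A tibble with one row per sequence (1300 rows).
#' @export
build_exp2_manifest <- function(seed, material = make_material(seed)) {
  with_seed(seed, {
    n <- 1300L
    grid <- tidyr::crossing(condition = exp2_conditions,
                            pitch_level = exp2_pitch_levels)
    cell <- sample(nrow(grid), n, replace = TRUE)
    speaker_id <- sample(8L, n, replace = TRUE)
    digits <- vapply(seq_len(n), function(i) {
      paste(sample(1:9, 6, replace = TRUE), collapse = "")
    }, character(1))
    out <- tibble::tibble(
      stimulus_id = sprintf("e2_%04d", seq_len(n)),
      experiment = 2L,
      speaker_id = speaker_id,
      digits = digits,
      condition = grid$condition[cell],
      pitch_level = grid$pitch_level[cell],
      snr_db = stats::runif(n, -6, 15),
      am_freq_hz = stats::runif(n, 50, 150),
      am_depth = stats::runif(n, 0.3, 0.6),
      sub_ratio = 2L,
      sub_depth = stats::runif(n, 0.3, 0.5),
      jitter_depth_st = stats::runif(n, 1, 4),
      jitter_rate_hz = 1000,
      rolloff_db_oct = 9,
      source_noise_db = -30,
      seed = vapply(seq_len(n), function(i) derive_seed(seed, 100000L + i),
                    integer(1))
    ) |>
      dplyr::mutate(
        pitch_shift_oct = dplyr::if_else(
          .data$condition == "whisper", 0,
          c(original = 0, up1 = 1, `up1.5` = 1.5)[.data$pitch_level]
        )
      )
    out$duration_s <- vapply(seq_len(n), function(i) {
      exp2_trial_plan(out[i, ], material)$total_duration_s
    }, numeric(1))
    out
  })
}

# Deterministic per-trial layout for a word-sequence record: token durations
# from the material, pauses and per-digit jump parameters from the record
# seed. Used identically by the manifest (for duration) and the renderer.
exp2_trial_plan <- function(record, material) {
  tokens <- material$digit_tokens
  digs <- strsplit(record$digits, "")[[1]]
  rows <- purrr::map_dfr(digs, function(d) {
    tokens[tokens$speaker_id == record$speaker_id & tokens$digit == d, ]
  })
  with_seed(record$seed, {
    pauses <- stats::runif(5, 0.05, 0.2)
    jumps <- tibble::tibble(
      point = stats::runif(6, 0.25, 0.75),
      magnitude = stats::runif(6, 3, 12),
      direction = sample(c("up", "down"), 6, replace = TRUE)
    )
    list(tokens = rows, pauses = pauses, jumps = jumps,
         noise_seed = derive_seed(record$seed, 17L),
         total_duration_s = sum(rows$duration_s) +
           sum(round(pauses * ROUGHSPEECH_SR)) / ROUGHSPEECH_SR)
  })
}

#' Stimulus manifest for the sentence-transcription experiment
#'
#' Crosses the 100 sentences with 12 conditions — original, resynthesized
#' without NLP, frequency jumps, mixed, and each of whisper / AM /
#' subharmonics / chaos in continuous and intermittent variants — for 1200
#' stimuli. Jump plans (about five alternating jumps of 0.5-12 st), episode
#' windows and manipulation parameters are drawn at render time from the
#' record seed. The two noise arms (quiet, masking noise at 0 dB SNR) are a
#' presentation-time choice, not manifest rows.
#'
#' @param seed Integer master seed.
#' @param material A [make_material()] store; defaults to
#'   `make_material(seed)`.
#' @return A tibble with one row per stimulus (1200 rows).
#' @export
build_exp3_manifest <- function(seed, material = make_material(seed)) {
  sent <- material$sentences
  durations <- vapply(sent$sentence_id, function(id) {
    plan <- sentence_plan(material, id)
    max(plan$start_s + plan$duration_s)
  }, numeric(1))
  with_seed(seed, {
    out <- tidyr::crossing(sentence_id = sent$sentence_id,
                           condition = exp3_conditions) |>
      dplyr::arrange(.data$sentence_id,
                     match(.data$condition, exp3_conditions)) |>
      dplyr::left_join(sent[, c("sentence_id", "text", "n_words")],
                       by = "sentence_id") |>
      dplyr::mutate(
        experiment = 3L,
        stimulus_id = sprintf("e3_%03d_%s", .data$sentence_id,
                              .data$condition),
        mode = dplyr::case_when(
          grepl("_continuous$", .data$condition) ~ "continuous",
          grepl("_intermittent$", .data$condition) ~ "intermittent",
          .data$condition %in% c("frequency_jumps", "mixed") ~ "intermittent",
          TRUE ~ NA_character_
        ),
        duration_s = durations[.data$sentence_id],
        rolloff_db_oct = 9,
        source_noise_db = -30,
        seed = purrr::map_int(dplyr::row_number(),
                              function(i) derive_seed(seed, 200000L + i))
      ) |>
      dplyr::select("stimulus_id", "experiment", "sentence_id", "condition",
                    "mode", "text", "n_words", "duration_s",
                    "rolloff_db_oct", "source_noise_db", "seed")
    out
  })
}

#' Write or read a stimulus manifest as CSV
#'
#' @param manifest A manifest tibble.
#' @param path File path.
#' @return `write_manifest_csv()` returns `path` invisibly;
#'   `read_manifest_csv()` returns the manifest tibble.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("digits" %in% names(df)) df$digits <- as.character(df$digits)
  tibble::as_tibble(df)
}
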