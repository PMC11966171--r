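#' Render a manifest row to audio
#'
#' Deterministically synthesizes the stimulus described by one manifest
#' record, composing the source, nonlinear-phonation, vocal-tract and mixing
#' stages as appropriate for the experiment:
#'
#' * Vowel experiment: constant-f0 harmonic source (rolloff 3 dB/oct, no
#'   noise) or whisper noise, NLP applied at source level, formant filter
#'   with linearly morphed diphthong tracks, Hilbert-envelope compression.
#' * Word experiment: per-digit f0 contours from the material, harmonic
#'   source at 9 dB/oct plus -30 dB white noise (or whisper), NLP per digit,
#'   synthetic spectral/amplitude envelopes transplanted onto each token,
#'   concatenation with 50-200 ms pauses, masking noise mixed at the
#'   record's SNR.
#' * Sentence experiment: whole-sentence contour with voiced/unvoiced gaps,
#'   jump plans and continuous/intermittent episodes, envelope
#'   transplantation; masking noise at 0 dB only when `noise = TRUE` (the
#'   noise arm is chosen at presentation, not in the manifest).
#'
#' Rendering the same record twice gives bit-identical samples.
#'
#' @param record One manifest row (from [build_exp1_manifest()],
#'   [build_exp2_manifest()] or [build_exp3_manifest()]).
#' @param material A [make_material()] store (experiments 2 and 3).
#' @param noise For sentence stimuli: mix in street-noise stand-in at
#'   0 dB SNR (default `FALSE`).
#' @param formant_table Vowel formant table (default
#'   [vowel_formant_table()]).
#' @return A [waveform()] at 22 050 Hz, peak-normalized.
#' @export
#' @examples
#' m <- build_exp1_manifest(1)
#' w <- render_stimulus(m[1, ])
render_stimulus <- function(record, material = NULL, noise = FALSE,
                            formant_table = vowel_formant_table()) {
  if (is.null(record$experiment) || length(record$experiment) != 1L) {
    stop("record must be a single manifest row")
  }
  switch(as.character(record$experiment),
         "1" = render_exp1(record, formant_table),
         "2" = render_exp2(record, material),
         "3" = render_exp3(record, material, noise, formant_table),
         stop("unknown experiment: ", record$experiment))
}

render_exp1 <- function(record, formant_table) {
  sr <- ROUGHSPEECH_SR
  with_seed(record$seed, {
    contour <- f0_contour(c(0, record$duration_s),
                          rep(record$f0_hz, 2))
    track <- interpolate_f0(contour, sr, record$duration_s)
    source <- switch(
      record$condition,
      tonal = synth_harmonics(track, record$rolloff_db_oct, sr),
      am = apply_am(synth_harmonics(track, record$rolloff_db_oct, sr),
                    record$am_freq_hz, record$am_depth),
      subharmonics = apply_subharmonics(track, record$rolloff_db_oct, sr,
                                        record$sub_ratio, record$sub_depth),
      chaos = synth_harmonics(
        apply_jitter(track, record$jitter_depth_st, record$jitter_rate_hz,
                     sr),
        record$rolloff_db_oct, sr),
      whisper = whisper_source(record$duration_s, sr),
      stop("unknown vowel-experiment condition: ", record$condition)
    )
    tracks <- morph_formant_tracks(
      vowel_formants(record$vowel_from, formant_table),
      vowel_formants(record$vowel_to, formant_table),
      record$morph, n_frames = 20L
    )
    out <- formant_filter(source, tracks)
    normalize_peak(compress_dynamics(out, window = 0.05))
  })
}

# One word token: source synthesis + NLP + envelope transplant. `jump` is a
# one-row tibble or NULL.
render_token <- function(token, record, jump, formant_table) {
  sr <- ROUGHSPEECH_SR
  dur <- token$duration_s
  vf <- vowel_formants(token$vowel, formant_table)
  env <- synthetic_envelope(dur, sr, vf$F * token$formant_scale,
                            vf$B * token$formant_scale)
  if (record$condition == "whisper") {
    src <- whisper_source(dur, sr)
  } else {
    shift <- 2^record$pitch_shift_oct
    contour <- f0_contour(c(0, dur),
                          c(token$f0_start_hz, token$f0_end_hz) * shift)
    if (record$condition == "frequency_jump" && !is.null(jump)) {
      contour <- apply_frequency_jump(contour, jump$point, jump$magnitude,
                                      jump$direction)
    }
    track <- interpolate_f0(contour, sr, dur)
    if (record$condition == "chaos") {
      track <- apply_jitter(track, record$jitter_depth_st,
                            record$jitter_rate_hz, sr)
    }
    src <- if (record$condition == "subharmonics") {
      apply_subharmonics(track, record$rolloff_db_oct, sr,
                         record$sub_ratio, record$sub_depth)
    } else {
      synth_harmonics(track, record$rolloff_db_oct, sr)
    }
    src <- add_source_noise(src, record$source_noise_db)
    if (record$condition == "am") {
      src <- apply_am(src, record$am_freq_hz, record$am_depth)
    }
  }
  transplant_envelopes(src, env)
}

render_exp2 <- function(record, material) {
  if (is.null(material)) stop("word-experiment rendering needs the material store")
  sr <- ROUGHSPEECH_SR
  plan <- exp2_trial_plan(record, material)
  formant_table <- vowel_formant_table()
  with_seed(derive_seed(record$seed, 23L), {
    tokens <- lapply(seq_len(nrow(plan$tokens)), function(i) {
      render_token(plan$tokens[i, ], record, plan$jumps[i, ], formant_table)
    })
    seq_audio <- concat_with_fixed_pauses(tokens, plan$pauses)
    nz <- with_seed(plan$noise_seed, {
      generate_masking_noise(duration(seq_audio$wave) + 0.05, sr)
    })
    mix_at_snr(seq_audio$wave, nz, record$snr_db)
  })
}

# Deterministic variant of concatenate_with_pauses for pre-drawn pauses.
concat_with_fixed_pauses <- function(tokens, pauses) {
  sr <- tokens[[1]]$sample_rate
  pieces <- list()
  starts <- numeric(length(tokens))
  t_cursor <- 0
  for (i in seq_along(tokens)) {
    starts[i] <- t_cursor
    pieces[[length(pieces) + 1L]] <- tokens[[i]]$samples
    t_cursor <- t_cursor + duration(tokens[[i]])
    if (i < length(tokens)) {
      np <- round(pauses[i] * sr)
      pieces[[length(pieces) + 1L]] <- numeric(np)
      t_cursor <- t_cursor + np / sr
    }
  }
  list(wave = waveform(unlist(pieces), sr),
       boundaries = tibble::tibble(
         token_index = seq_along(tokens), start_s = starts,
         end_s = starts + vapply(tokens, duration, numeric(1))))
}

render_exp3 <- function(record, material, noise, formant_table) {
  if (is.null(material)) {
    stop("sentence-experiment rendering needs the material store")
  }
  sr <- ROUGHSPEECH_SR
  plan <- sentence_plan(material, record$sentence_id)
  env <- sentence_envelope(plan, sr, formant_table)
  contour <- sentence_contour(plan)
  total <- (ncol(env$spectral) - 1L) * env$hop / sr + env$n_fft / sr
  with_seed(record$seed, {
    cond <- record$condition
    eps <- if (!is.na(record$mode) && record$mode == "intermittent") {
      place_episodes(total, "intermittent")
    } else {
      episodes_continuous()
    }
    am_freq <- stats::runif(1, 50, 150)
    am_depth <- stats::runif(1, 0.3, 0.6)
    sub_depth <- stats::runif(1, 0.3, 0.5)
    jitter_depth <- stats::runif(1, 1, 4)
    if (cond %in% c("frequency_jumps", "mixed")) {
      jump_plan <- plan_jumps_alternating(contour, n_jumps = 5,
                                          magnitude_range = c(0.5, 12))
      contour <- apply_jump_plan(contour, jump_plan)
    }
    # in the mixed condition each episode gets its own NLP kind on top of
    # the frequency jumps
    chaos_eps <- sub_eps <- am_eps <- NULL
    if (cond == "mixed") {
      kinds <- sample(c("am", "subharmonics", "chaos"), nrow(eps),
                      replace = TRUE)
      pick <- function(kind) {
        sel <- eps[kinds == kind, , drop = FALSE]
        if (nrow(sel) > 0) sel else NULL
      }
      chaos_eps <- pick("chaos")
      sub_eps <- pick("subharmonics")
      am_eps <- pick("am")
    } else if (cond %in% c("chaos_continuous", "chaos_intermittent")) {
      chaos_eps <- eps
    } else if (cond %in% c("subharmonics_continuous",
                           "subharmonics_intermittent")) {
      sub_eps <- eps
    } else if (cond %in% c("am_continuous", "am_intermittent")) {
      am_eps <- eps
    }
    track <- interpolate_f0(contour, sr, total)
    if (!is.null(chaos_eps)) {
      track <- apply_jitter(track, jitter_depth, 1000, sr,
                            episodes = chaos_eps)
    }
    src <- if (!is.null(sub_eps)) {
      apply_subharmonics(track, record$rolloff_db_oct, sr, 2L, sub_depth,
                         episodes = sub_eps)
    } else if (cond == "whisper_continuous") {
      whisper_source(total, sr)
    } else {
      synth_harmonics(track, record$rolloff_db_oct, sr)
    }
    if (cond != "whisper_continuous") {
      src <- add_source_noise(src, record$source_noise_db)
    }
    if (cond == "whisper_intermittent") {
      wh <- whisper_source(total, sr)
      wh <- waveform(wh$samples * (rms(src) / rms(wh)), sr)
      mask <- episode_mask(length(src$samples), eps, sr)
      src <- waveform(src$samples * (1 - mask) + wh$samples * mask, sr)
    }
    if (!is.null(am_eps)) {
      src <- apply_am(src, am_freq, am_depth, episodes = am_eps)
    }
    out <- transplant_envelopes(src, env)
    if (noise) {
      nz <- generate_masking_noise(duration(out) + 0.05, sr)
      out <- mix_at_snr(out, nz, 0)
    }
    normalize_peak(out)
  })
}
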