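# Synthetic speaker material: the stand-in for the recorded digit and
# sentence corpora. Everything here is parametric (f0 anchors, durations,
# per-token formant sets, envelope shapes) and deterministic per seed, so a
# material object is small and any stimulus is reproducible from its
# manifest row.

digit_vowels <- c("1" = "a", "2" = "u", "3" = "i", "4" = "o", "5" = "a",
                  "6" = "i", "7" = "e", "8" = "e", "9" = "a")

#' Generate synthetic speaker material
#'
#' Builds the material store the renderers draw from: eight computer-voice
#' speaker profiles (four male, four female), per-speaker digit tokens
#' (1-9, durations chosen so that six-digit sequences with 50-200 ms pauses
#' land in the 2.6-4.4 s range), and a sentence table for the transcription
#' experiment (one female voice). Tokens carry f0 anchors with declination,
#' a vowel-quality label that fixes their formant set, and an amplitude
#' envelope shape; spectral envelopes are constructed from these parameters
#' at render time via [synthetic_envelope()]. This material emulates the
#' f0 contours and envelopes that would be extracted from recordings; it is
#' synthetic throughout.
#'
#' @param seed Integer seed; the material is a pure function of it.
#' @return An object of class `speech_material`: list with `speakers`,
#'   `digit_tokens`, `sentences` tibbles and the generating `seed`.
#' @export
#' @examples
#' mat <- make_material(1)
#' mat$speakers
make_material <- function(seed) {
  with_seed(seed, {
    speakers <- tibble::tibble(
      speaker_id = 1:8,
      sex = rep(c("m", "f"), each = 4),
      base_f0_hz = c(stats::runif(4, 100, 140), stats::runif(4, 180, 240)),
      formant_scale = c(stats::runif(4, 0.96, 1.04),
                        stats::runif(4, 1.12, 1.22))
    )
    digit_tokens <- tidyr::crossing(speaker_id = 1:8,
                                    digit = as.character(1:9)) |>
      dplyr::left_join(speakers, by = "speaker_id") |>
      dplyr::mutate(
        duration_s = stats::runif(dplyr::n(), 0.40, 0.56),
        vowel = digit_vowels[.data$digit],
        # gentle declination with per-token scatter
        f0_start_hz = .data$base_f0_hz *
          2^(stats::runif(dplyr::n(), 0.05, 0.2)),
        f0_end_hz = .data$base_f0_hz *
          2^(stats::runif(dplyr::n(), -0.2, -0.05))
      ) |>
      dplyr::select("speaker_id", "sex", "digit", "vowel", "duration_s",
                    "f0_start_hz", "f0_end_hz", "formant_scale")
    texts <- sentence_texts()
    sentences <- tibble::tibble(
      sentence_id = seq_along(texts),
      text = texts,
      n_words = lengths(strsplit(texts, " ")),
      base_f0_hz = stats::runif(length(texts), 195, 225),  # female speaker
      seed = vapply(seq_along(texts),
                    function(i) derive_seed(seed, 7000L + i), integer(1))
    )
    structure(list(speakers = speakers, digit_tokens = digit_tokens,
                   sentences = sentences, seed = seed),
              class = "speech_material")
  })
}

#' @export
print.speech_material <- function(x, ...) {
  cat(sprintf(
    "<speech_material: %d speakers, %d digit tokens, %d sentences (seed %d)>\n",
    nrow(x$speakers), nrow(x$digit_tokens), nrow(x$sentences), x$seed))
  invisible(x)
}

#' Single-clause sentence texts for the transcription experiment
#'
#' One hundred short sentences: four printed examples from the experiment's
#' materials plus ninety-six deterministic synthetic word strings assembled
#' from a small vocabulary (the original recorded corpus is external and not
#' shipped). All sentences are 6-10 words long.
#'
#' @return Character vector of length 100.
#' @export
sentence_texts <- function() {
  fixed <- c(
    "the jacket hung on the back of the wide chair",
    "at that high level the air is pure",
    "drop the two when you add the figures",
    "an abrupt start does not win the prize"
  )
  subjects <- c("the boy", "a girl", "the old man", "her friend", "the cook",
                "a young nurse", "the tall guard", "his dog")
  verbs <- c("carried", "found", "dropped", "painted", "watched", "moved",
             "cleaned", "opened")
  objects <- c("the small box", "a green lamp", "the heavy chair",
               "two ripe plums", "the long rope", "a paper bag",
               "the round clock", "one sharp knife")
  places <- c("near the gate", "by the lake", "in the barn",
              "on the porch", "down the road", "past the mill",
              "under the bridge", "at the shop")
  out <- character(96)
  for (i in seq_len(96)) {
    # fixed mixed-radix enumeration: deterministic, no RNG involved
    s <- subjects[(i - 1L) %% 8L + 1L]
    v <- verbs[((i - 1L) %/% 8L + i) %% 8L + 1L]
    o <- objects[((i - 1L) %/% 3L) %% 8L + 1L]
    p <- places[((i - 1L) %/% 5L + 2L * i) %% 8L + 1L]
    out[i] <- paste(s, v, o, p)
  }
  c(fixed, out)
}

# Deterministic word -> vowel-quality mapping (simple character hash).
word_vowel <- function(word) {
  labels <- c("a", "o", "e", "i", "u")
  h <- sum(utf8ToInt(word) * seq_len(nchar(word)))
  labels[h %% 5L + 1L]
}

#' Build a synthetic envelope set from token parameters
#'
#' Constructs the spectral and amplitude envelopes of a token directly from
#' its formant set and an amplitude shape (attack-sustain-release), on the
#' same time-frequency grid [extract_envelopes()] would use. This is how the
#' synthetic material stands in for envelopes extracted from recordings.
#'
#' @param duration Token duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param formant_hz Formant frequencies in Hz (extended to Nyquist
#'   internally).
#' @param bw_hz Formant bandwidths in Hz (defaults to `50 + 0.05 * F`).
#' @param amp Amplitude-shape vector resampled to the frame grid, or `NULL`
#'   for a default attack-release syllable shape.
#' @param n_fft STFT size (default 1024).
#' @return An `envelope_set` (see [extract_envelopes()]).
#' @export
synthetic_envelope <- function(duration, sample_rate, formant_hz,
                               bw_hz = NULL, amp = NULL, n_fft = 1024L) {
  n <- round(duration * sample_rate)
  hop <- n_fft %/% 4L
  n_frames <- n_stft_frames(n, n_fft, hop)
  freqs <- seq(0, sample_rate / 2, length.out = n_fft %/% 2L + 1L)
  nyq <- sample_rate / 2
  if (length(formant_hz) >= 4L && max(formant_hz) < nyq) {
    formant_hz <- extend_formants(formant_hz, nyq)
  }
  if (is.null(bw_hz)) bw_hz <- 50 + 0.05 * formant_hz
  if (length(bw_hz) < length(formant_hz)) {
    bw_hz <- c(bw_hz, 50 + 0.05 * formant_hz[(length(bw_hz) + 1L):length(formant_hz)])
  }
  shape <- tract_gain(freqs, formant_hz, bw_hz)
  if (is.null(amp)) {
    x <- seq(0, 1, length.out = n_frames)
    amp <- sqrt(pmin(x / 0.2, 1, (1 - x) / 0.25))  # attack-sustain-release
    amp[!is.finite(amp) | amp < 0] <- 0
  } else {
    amp <- stats::approx(seq(0, 1, length.out = length(amp)), amp,
                         xout = seq(0, 1, length.out = n_frames))$y
  }
  amp <- pmax(amp, 1e-3) * 0.1
  spectral <- outer(shape, amp)
  structure(list(spectral = spectral, amplitude = amp, freqs = freqs,
                 times = (seq_len(n_frames) - 1L) * hop / sample_rate +
                   n_fft / 2 / sample_rate,
                 n_fft = n_fft, hop = hop, sample_rate = sample_rate,
                 freq_window = 300, time_window = 0.2),
            class = "envelope_set")
}

#' Word-level plan of a sentence token sequence
#'
#' Lays the sentence's words out in time (word durations 0.20-0.36 s, gaps
#' 30-80 ms, so sentences span roughly 1.8-3.5 s) and assigns each word a
#' vowel-quality formant set; pure
#' function of the material seed and sentence id. The resulting plan drives
#' both the sentence f0 contour and its synthetic envelopes.
#'
#' @param material A [make_material()] object.
#' @param sentence_id Sentence id in 1-100.
#' @return A tibble: `word`, `start_s`, `duration_s`, `vowel`, `f0_mid_hz`.
#' @export
sentence_plan <- function(material, sentence_id) {
  row <- material$sentences[material$sentences$sentence_id == sentence_id, ]
  if (nrow(row) != 1L) stop("unknown sentence_id: ", sentence_id)
  words <- strsplit(row$text, " ")[[1]]
  with_seed(row$seed, {
    durs <- stats::runif(length(words), 0.20, 0.36)
    gaps <- stats::runif(length(words), 0.03, 0.08)
    gaps[1] <- 0.02
    starts <- cumsum(gaps) + c(0, cumsum(durs))[seq_along(words)]
    # sentence-level declination with word accents
    frac <- (starts + durs / 2) / (starts[length(words)] + durs[length(words)])
    f0_mid <- row$base_f0_hz * 2^(0.15 - 0.3 * frac +
                                    stats::runif(length(words), -0.05, 0.08))
    tibble::tibble(word = words, start_s = starts, duration_s = durs,
                   vowel = vapply(words, word_vowel, character(1)),
                   f0_mid_hz = f0_mid)
  })
}

# Full-sentence f0 contour (voiced words, unvoiced gaps) from a plan.
sentence_contour <- function(plan) {
  times <- c()
  values <- c()
  voiced <- c()
  for (i in seq_len(nrow(plan))) {
    t0 <- plan$start_s[i]
    t1 <- t0 + plan$duration_s[i]
    f <- plan$f0_mid_hz[i]
    times <- c(times, t0, (t0 + t1) / 2, t1)
    values <- c(values, f * 2^0.04, f, f * 2^-0.05)
    voiced <- c(voiced, TRUE, TRUE, TRUE)
    if (i < nrow(plan)) {
      gap_t <- (t1 + plan$start_s[i + 1]) / 2
      times <- c(times, gap_t)
      values <- c(values, f)
      voiced <- c(voiced, FALSE)
    }
  }
  f0_contour(times, values, voiced)
}

# Whole-sentence envelope set: per-frame formant shape of the active word,
# near-silence in gaps.
sentence_envelope <- function(plan, sample_rate, formant_table, n_fft = 1024L) {
  total <- max(plan$start_s + plan$duration_s) + 0.05
  n <- round(total * sample_rate)
  hop <- n_fft %/% 4L
  n_frames <- n_stft_frames(n, n_fft, hop)
  freqs <- seq(0, sample_rate / 2, length.out = n_fft %/% 2L + 1L)
  t_frames <- (seq_len(n_frames) - 1L) * hop / sample_rate
  spectral <- matrix(1e-4, nrow = length(freqs), ncol = n_frames)
  amp <- rep(1e-3, n_frames)
  nyq <- sample_rate / 2
  shapes <- lapply(unique(plan$vowel), function(vl) {
    vf <- vowel_formants(vl, formant_table)
    F <- extend_formants(vf$F, nyq)
    B <- c(vf$B, 50 + 0.05 * F[5:length(F)])
    tract_gain(freqs, F, B)
  })
  names(shapes) <- unique(plan$vowel)
  for (i in seq_len(nrow(plan))) {
    t0 <- plan$start_s[i]
    t1 <- t0 + plan$duration_s[i]
    j <- which(t_frames >= t0 & t_frames <= t1)
    if (length(j) == 0L) next
    x <- (t_frames[j] - t0) / (t1 - t0)
    a <- sqrt(pmin(x / 0.2, 1, (1 - x) / 0.25))
    a[!is.finite(a) | a < 0] <- 0
    a <- pmax(a, 1e-3) * 0.1
    spectral[, j] <- outer(shapes[[plan$vowel[i]]], a)
    amp[j] <- a
  }
  structure(list(spectral = spectral, amplitude = amp, freqs = freqs,
                 times = t_frames + n_fft / 2 / sample_rate,
                 n_fft = n_fft, hop = hop, sample_rate = sample_rate,
                 freq_window = 300, time_window = 0.2),
            class = "envelope_set")
}
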