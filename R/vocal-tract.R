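#' Default vowel formant table
#'
#' Typical adult-male formant frequencies for the five vowel qualities
#' /a o e i u/ used by the vowel-discrimination experiment, with bandwidths
#' following `B = 50 + 0.05 * F` Hz. The table is a plain tibble so users can
#' supply their own measurements anywhere a vowel label is accepted; every
#' function that needs formant values reads them from a table of this shape.
#'
#' @return A tibble with columns `label`, `F1`..`F4`, `B1`..`B4`.
#' @export
#' @examples
#' vowel_formant_table()
vowel_formant_table <- function() {
  tb <- tibble::tribble(
    ~label,  ~F1,  ~F2,  ~F3,  ~F4,
    "a",     800, 1200, 2500, 3500,
    "o",     450,  800, 2600, 3300,
    "e",     450, 1950, 2700, 3600,
    "i",     280, 2250, 2900, 3700,
    "u",     310,  750, 2350, 3300
  )
  for (k in 1:4) tb[[paste0("B", k)]] <- 50 + 0.05 * tb[[paste0("F", k)]]
  tb
}

#' Look up one vowel's formants
#'
#' @param label One of the labels in `table` (default /a o e i u/).
#' @param table A formant table shaped like [vowel_formant_table()].
#' @return A list with numeric vectors `F` (Hz) and `B` (Hz), length 4.
#' @export
vowel_formants <- function(label, table = vowel_formant_table()) {
  row <- table[table$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown vowel label: ", label)
  F <- as.numeric(row[paste0("F", 1:4)])
  B <- as.numeric(row[paste0("B", 1:4)])
  if (any(diff(F) <= 0) || any(F <= 0)) stop("formants must be increasing and positive")
  list(F = F, B = B)
}

#' Extend a formant series to the Nyquist frequency
#'
#' Formants above F4 are added at `F4 + m * delta`, where `delta` is the mean
#' spacing of the measured formants, `mean(c(F2-F1, F3-F2, F4-F3))`, until the
#' next formant would reach Nyquist.
#'
#' @param formants Numeric vector of at least 4 ascending formant
#'   frequencies in Hz, all below `nyquist`.
#' @param nyquist Nyquist frequency in Hz.
#' @return Numeric vector: the input formants followed by the extrapolated
#'   ones, all strictly below `nyquist`.
#' @export
#' @examples
#' extend_formants(c(500, 1500, 2500, 3500), 11025)
extend_formants <- function(formants, nyquist) {
  if (length(formants) < 4L) stop("need at least 4 formants")
  if (any(formants >= nyquist)) stop("measured formants must lie below Nyquist")
  delta <- mean(diff(formants[1:4]))
  if (delta <= 0) stop("formant spacing must be positive")
  top <- formants[length(formants)]
  if (top + delta >= nyquist) return(formants)
  extra <- seq(top + delta, nyquist, by = delta)
  extra <- extra[extra < nyquist]
  c(formants, extra)
}

#' Linearly morphed formant tracks for a diphthong
#'
#' Formant `i` at time fraction `tau` equals
#' `F_from[i] + tau * morph * (F_to[i] - F_from[i])`: `morph = 0` is a static
#' monophthong, `morph = 1` glides all the way to the second vowel, and
#' intermediate values stop part-way (the experiment quantizes morph to steps
#' of 0.1).
#'
#' @param vowel_from,vowel_to Lists with `F` and `B` from [vowel_formants()].
#' @param morph Morph fraction in \[0, 1\].
#' @param n_frames Number of time frames for the tracks.
#' @return A tibble with columns `frame`, `tau`, `formant`, `freq_hz`,
#'   `bw_hz`.
#' @export
morph_formant_tracks <- function(vowel_from, vowel_to, morph, n_frames) {
  if (morph < 0 || morph > 1) stop("morph must lie in [0, 1]")
  if (n_frames < 1) stop("need at least one frame")
  tau <- if (n_frames == 1L) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
  nf <- length(vowel_from$F)
  tidyr::crossing(frame = seq_len(n_frames), formant = seq_len(nf)) |>
    dplyr::mutate(
      tau = tau[.data$frame],
      freq_hz = vowel_from$F[.data$formant] +
        .data$tau * morph * (vowel_to$F[.data$formant] -
                               vowel_from$F[.data$formant]),
      bw_hz = vowel_from$B[.data$formant] +
        .data$tau * morph * (vowel_to$B[.data$formant] -
                               vowel_from$B[.data$formant])
    ) |>
    dplyr::select("frame", "tau", "formant", "freq_hz", "bw_hz")
}

# Vocal-tract magnitude response on a frequency grid: a sum of Lorentzian
# resonances (peak gain 1 at each formant) over a -80 dB broadband floor.
tract_gain <- function(freqs, formant_hz, bw_hz) {
  g <- rep(1e-4, length(freqs))
  for (i in seq_along(formant_hz)) {
    g <- g + 1 / (1 + ((freqs - formant_hz[i]) / (bw_hz[i] / 2))^2)
  }
  g
}

#' Impose a (possibly time-varying) formant filter on a source
#'
#' Realized as frame-wise spectral multiplication: each STFT frame of the
#' source is multiplied by a vocal-tract magnitude response with Lorentzian
#' resonance peaks at the track frequencies, then inverted by overlap-add.
#' Formants above the highest track value are extrapolated to Nyquist at the
#' vowel's mean formant spacing when `extend = TRUE`.
#'
#' @param source A [waveform()] (harmonic source or noise).
#' @param tracks Formant tracks from [morph_formant_tracks()], or a list from
#'   [vowel_formants()] for a static filter.
#' @param extend Extend formants to Nyquist via [extend_formants()]
#'   (default `TRUE`).
#' @param n_fft STFT size (default 1024).
#' @return A filtered [waveform()], peak-normalized.
#' @export
formant_filter <- function(source, tracks, extend = TRUE, n_fft = 1024L) {
  stopifnot(inherits(source, "waveform"))
  nyquist <- source$sample_rate / 2
  if (!is.data.frame(tracks)) {
    tracks <- morph_formant_tracks(tracks, tracks, 0, 2L)
  }
  if (any(tracks$freq_hz >= nyquist)) {
    stop("formant frequency at or above Nyquist")
  }
  S <- stft(source$samples, source$sample_rate, n_fft = n_fft)
  n_frames <- ncol(S$frames)
  track_frames <- sort(unique(tracks$frame))
  # map STFT frames onto track frames by time fraction
  pos <- seq(0, 1, length.out = n_frames)
  for (j in seq_len(n_frames)) {
    tf <- track_frames[pmin(length(track_frames),
                            1L + floor(pos[j] * (length(track_frames) - 1L) + 0.5))]
    fr <- tracks[tracks$frame == tf, ]
    Fv <- fr$freq_hz[order(fr$formant)]
    Bv <- fr$bw_hz[order(fr$formant)]
    if (extend && length(Fv) >= 4L) {
      ext <- extend_formants(Fv, nyquist)
      n_extra <- length(ext) - length(Fv)
      if (n_extra > 0) {
        Bv <- c(Bv, 50 + 0.05 * ext[(length(Fv) + 1):length(ext)])
        Fv <- ext
      }
    }
    S$frames[, j] <- S$frames[, j] * tract_gain(S$freqs, Fv, Bv)
  }
  normalize_peak(waveform(istft(S), source$sample_rate))
}

#' Extract smoothed spectral and amplitude envelopes
#'
#' The spectral envelope is the STFT magnitude smoothed across frequency with
#' a 300 Hz running-mean kernel; the amplitude envelope is the per-frame RMS
#' smoothed over a 200 ms time window (the smoothing windows used for
#' resynthesis of the recorded material).
#'
#' @param audio A non-silent [waveform()].
#' @param freq_window Frequency smoothing window in Hz (default 300).
#' @param time_window Amplitude smoothing window in seconds (default 0.2).
#' @param n_fft STFT size (default 1024).
#' @return An object of class `envelope_set`: list with `spectral` (freq x
#'   frame magnitude matrix), `amplitude` (per-frame RMS), `freqs`, `times`,
#'   and the STFT parameters.
#' @export
extract_envelopes <- function(audio, freq_window = 300, time_window = 0.2,
                              n_fft = 1024L) {
  stopifnot(inherits(audio, "waveform"))
  if (rms(audio) == 0) stop("cannot extract envelopes from silent audio")
  S <- stft(audio$samples, audio$sample_rate, n_fft = n_fft)
  mag <- Mod(S$frames)
  bin_hz <- audio$sample_rate / n_fft
  kbins <- max(1L, round(freq_window / bin_hz))
  spectral <- apply(mag, 2, smooth_moving, window = kbins)
  frame_rms <- sqrt(colMeans(mag^2))
  fps <- audio$sample_rate / S$hop
  amplitude <- smooth_moving(frame_rms, round(time_window * fps))
  structure(list(spectral = spectral, amplitude = amplitude,
                 freqs = S$freqs, times = S$times, n_fft = n_fft,
                 hop = S$hop, sample_rate = audio$sample_rate,
                 freq_window = freq_window, time_window = time_window),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf(
    "<envelope_set: %d freq bins x %d frames, %g Hz / %g s smoothing>\n",
    nrow(x$spectral), ncol(x$spectral), x$freq_window, x$time_window))
  invisible(x)
}

#' Transplant spectral and amplitude envelopes onto a source
#'
#' Whitens the source frame-by-frame by its own smoothed spectral envelope
#' and imposes the target envelopes instead: the output's smoothed spectrum
#' follows the target spectral envelope and its frame-level amplitude follows
#' the target amplitude envelope. This is how the synthetic voice sources
#' acquire the formants and syllable rhythm of the original recordings.
#'
#' @param source A [waveform()]; its duration must be within 10% of the
#'   envelope duration (frames are mapped proportionally).
#' @param env An `envelope_set` from [extract_envelopes()].
#' @return A [waveform()], peak-normalized.
#' @export
transplant_envelopes <- function(source, env) {
  stopifnot(inherits(source, "waveform"), inherits(env, "envelope_set"))
  if (source$sample_rate != env$sample_rate) {
    stop("sample-rate mismatch between source and envelopes")
  }
  env_dur <- (ncol(env$spectral) - 1L) * env$hop / env$sample_rate +
    env$n_fft / env$sample_rate
  if (abs(duration(source) - env_dur) > 0.1 * env_dur) {
    stop("source duration differs from envelope duration by more than 10%")
  }
  S <- stft(source$samples, source$sample_rate, n_fft = env$n_fft)
  mag <- Mod(S$frames)
  bin_hz <- source$sample_rate / env$n_fft
  kbins <- max(1L, round(env$freq_window / bin_hz))
  own <- apply(mag, 2, smooth_moving, window = kbins)
  n_frames <- ncol(S$frames)
  idx <- pmin(ncol(env$spectral),
              pmax(1L, round(seq(1, ncol(env$spectral), length.out = n_frames))))
  eps <- 1e-6 * max(own)
  for (j in seq_len(n_frames)) {
    tgt <- env$spectral[, idx[j]]
    S$frames[, j] <- S$frames[, j] * tgt / pmax(own[, j], eps)
  }
  # impose the amplitude envelope on the whitened frames
  mag2 <- Mod(S$frames)
  frame_rms <- sqrt(colMeans(mag2^2))
  tgt_amp <- env$amplitude[idx]
  scale <- tgt_amp / pmax(frame_rms, 1e-6 * max(frame_rms))
  S$frames <- sweep(S$frames, 2, scale, `*`)
  normalize_peak(waveform(istft(S), source$sample_rate))
}

#' Compress dynamics with a smoothed Hilbert envelope
#'
#' Divides the signal by its smoothed instantaneous (analytic-signal)
#' envelope, floored at 1% of the envelope peak to avoid blowing up silences,
#' then rescales to the input RMS. Applied to every synthesized vowel with a
#' 50 ms smoothing window to avoid large intensity changes in diphthongs.
#'
#' @param wave A non-silent [waveform()].
#' @param window Envelope smoothing window in seconds (default 0.05).
#' @param floor_frac Envelope floor as a fraction of its peak (default 0.01).
#' @return A compressed [waveform()] with the same RMS as the input.
#' @export
compress_dynamics <- function(wave, window = 0.05, floor_frac = 0.01) {
  stopifnot(inherits(wave, "waveform"))
  if (window <= 0) stop("window must be positive")
  if (rms(wave) == 0) stop("cannot compress silent audio")
  env <- analytic_envelope(wave$samples)
  env <- smooth_moving(env, window * wave$sample_rate)
  flo <- floor_frac * max(env)
  out <- wave$samples / pmax(env, flo)
  out <- out * (rms(wave) / sqrt(mean(out^2)))
  waveform(out, wave$sample_rate)
}
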