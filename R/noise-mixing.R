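#' Generate masking noise with a piecewise spectral profile
#'
#' Builds the required magnitude profile in the frequency domain — flat up to
#' `corner`, then sloping at `slope` dB per kHz — assigns random phases, and
#' converts to the time domain with an inverse short-time Fourier transform.
#' The word experiment uses a corner of 1.2 kHz and a slope of -6 dB/kHz.
#'
#' @param duration Noise duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param corner Corner frequency in Hz: the spectrum is flat below it.
#' @param slope Spectral slope above the corner in dB per kHz (negative =
#'   falling).
#' @param n_fft STFT size (default 1024).
#' @return A [waveform()], peak-normalized.
#' @export
#' @examples
#' set.seed(1)
#' nz <- generate_masking_noise(1, 22050)
generate_masking_noise <- function(duration, sample_rate, corner = 1200,
                                   slope = -6, n_fft = 1024L) {
  if (duration <= 0) stop("duration must be positive")
  if (corner <= 0 || corner >= sample_rate / 2) {
    stop("corner frequency must lie between 0 and Nyquist")
  }
  n <- round(duration * sample_rate)
  freqs <- seq(0, sample_rate / 2, length.out = n_fft %/% 2L + 1L)
  profile <- ifelse(freqs <= corner, 1,
                    db_to_ratio(slope * (freqs - corner) / 1000))
  hop <- n_fft %/% 4L
  n_frames <- ceiling(n / hop) + 4L
  frames <- matrix(complex(real = 0), nrow = length(freqs), ncol = n_frames)
  for (j in seq_len(n_frames)) {
    phases <- stats::runif(length(freqs), 0, 2 * pi)
    # real signal: DC and Nyquist bins get zero phase
    phases[c(1L, length(freqs))] <- 0
    frames[, j] <- profile * exp(1i * phases)
  }
  S <- list(frames = frames, n_fft = n_fft, hop = hop,
            n_samples = (n_frames - 1L) * hop + n_fft,
            sample_rate = sample_rate)
  out <- istft(S)
  out <- out[seq_len(min(n, length(out)))]
  if (length(out) < n) out <- c(out, numeric(n - length(out)))
  normalize_peak(waveform(out, sample_rate))
}

#' Mix signal and noise at a target SNR
#'
#' Scales the noise so that `20*log10(RMS(signal)/RMS(noise))` equals `snr`,
#' adds it to the signal (noise truncated to the signal length), and
#' peak-normalizes the mixture. The word experiment drew SNR uniformly in
#' \[-6, 15\] dB; the sentence experiment's noisy arm used 0 dB.
#'
#' @param signal,noise [waveform()]s at the same sample rate; the noise must
#'   be at least as long as the signal.
#' @param snr Target signal-to-noise ratio in dB.
#' @return The peak-normalized mixture [waveform()].
#' @export
mix_at_snr <- function(signal, noise, snr) {
  stopifnot(inherits(signal, "waveform"), inherits(noise, "waveform"))
  if (signal$sample_rate != noise$sample_rate) stop("sample rates differ")
  if (length(noise$samples) < length(signal$samples)) {
    stop("noise must be at least as long as the signal")
  }
  if (!is.finite(snr)) stop("snr must be finite")
  s_rms <- rms(signal)
  nz <- noise$samples[seq_along(signal$samples)]
  n_rms <- sqrt(mean(nz^2))
  if (s_rms == 0 || n_rms == 0) stop("signal and noise must be non-silent")
  nz <- nz * (s_rms / n_rms) * db_to_ratio(-snr)
  normalize_peak(waveform(signal$samples + nz, signal$sample_rate))
}

#' Concatenate word tokens with random pauses
#'
#' Joins the tokens with silent pauses drawn uniformly from `pause_range`
#' (50-200 ms in the word experiment) and returns both the audio and a
#' boundary log from which every token span is recoverable.
#'
#' @param tokens A list of [waveform()]s at a common sample rate.
#' @param pause_range Pause duration range in seconds, default
#'   `c(0.05, 0.2)`.
#' @return A list with `wave` (the concatenated [waveform()]) and
#'   `boundaries` (tibble: `token_index`, `start_s`, `end_s`).
#' @export
concatenate_with_pauses <- function(tokens, pause_range = c(0.05, 0.2)) {
  if (length(tokens) == 0L) stop("need at least one token")
  sr <- tokens[[1]]$sample_rate
  if (!all(vapply(tokens, function(w) w$sample_rate == sr, logical(1)))) {
    stop("all tokens must share one sample rate")
  }
  n_pauses <- length(tokens) - 1L
  pauses <- if (n_pauses > 0) {
    stats::runif(n_pauses, pause_range[1], pause_range[2])
  } else numeric(0)
  pieces <- list()
  starts <- numeric(length(tokens))
  t_cursor <- 0
  for (i in seq_along(tokens)) {
    starts[i] <- t_cursor
    pieces[[length(pieces) + 1L]] <- tokens[[i]]$samples
    t_cursor <- t_cursor + duration(tokens[[i]])
    if (i <= n_pauses) {
      pieces[[length(pieces) + 1L]] <- numeric(round(pauses[i] * sr))
      t_cursor <- t_cursor + round(pauses[i] * sr) / sr
    }
  }
  ends <- starts + vapply(tokens, duration, numeric(1))
  list(
    wave = waveform(unlist(pieces), sr),
    boundaries = tibble::tibble(token_index = seq_along(tokens),
                                start_s = starts, end_s = ends)
  )
}
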