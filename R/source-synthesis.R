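#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic stage funnels through this so that any stimulus or
# simulation is exactly reproducible from its seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-record seed from (master seed, id) that stays inside the
# 32-bit integer range. Splittable enough for stimulus bookkeeping.
derive_seed <- function(master, id) {
  as.integer((as.numeric(master) * 48271 + as.numeric(id) * 16807) %% 2147483563) + 1L
}

#' Additive harmonic synthesis from a per-sample f0 track
#'
#' Builds the voiced part of the glottal source as a mixture of continuous
#' sine waves, one per harmonic, with phase accumulated as the cumulative
#' integral of instantaneous frequency (so slowly varying f0 never clicks).
#' Harmonic k is attenuated by `rolloff * log2(k)` dB relative to the
#' fundamental. The number of harmonics is capped so that no partial exceeds
#' the Nyquist frequency minus a 50 Hz guard band at the track's f0 peak.
#' Unvoiced (`NA`) spans come out as silence.
#'
#' @param f0_track Per-sample f0 in Hz (`NA` = unvoiced), e.g. from
#'   [interpolate_f0()].
#' @param rolloff Spectral rolloff in dB/octave (>= 0): 3 for the vowel
#'   experiment, 9 for word and sentence resynthesis.
#' @param sample_rate Sampling rate in Hz.
#' @param random_phase Use random initial phases per harmonic (default
#'   `FALSE`: deterministic zero phases).
#' @param extra_partials Optional tibble with columns `ratio` (frequency as a
#'   multiple of f0) and `amp` (linear amplitude relative to harmonic 1);
#'   used internally for subharmonic synthesis.
#' @return A [waveform()], peak-normalized to at most 1.
#' @export
#' @examples
#' tr <- rep(220, 22050)
#' w <- synth_harmonics(tr, rolloff = 9, sample_rate = 22050)
synth_harmonics <- function(f0_track, rolloff, sample_rate,
                            random_phase = FALSE, extra_partials = NULL) {
  if (rolloff < 0) stop("rolloff must be >= 0 dB/octave")
  n <- length(f0_track)
  if (n == 0L) stop("empty f0 track")
  nyquist <- sample_rate / 2
  voiced <- !is.na(f0_track)
  out <- numeric(n)
  if (any(voiced)) {
    f0_max <- max(f0_track[voiced])
    if (f0_max >= nyquist) stop("f0 reaches the Nyquist frequency")
    k_max <- floor((nyquist - 50) / f0_max)
    if (k_max < 1L) stop("no harmonic fits below Nyquist minus the guard band")
    partials <- tibble::tibble(
      ratio = seq_len(k_max),
      amp = db_to_ratio(-rolloff * log2(seq_len(k_max)))
    )
    if (!is.null(extra_partials)) {
      extra <- extra_partials[extra_partials$ratio * f0_max < nyquist - 50, ,
                              drop = FALSE]
      partials <- rbind(partials, extra)
    }
    f0_filled <- f0_track
    f0_filled[!voiced] <- 0
    phase_base <- 2 * pi * cumsum(f0_filled) / sample_rate
    for (i in seq_len(nrow(partials))) {
      phi0 <- if (random_phase) stats::runif(1, 0, 2 * pi) else 0
      out <- out + partials$amp[i] *
        sin(partials$ratio[i] * phase_base + phi0)
    }
    out[!voiced] <- 0
  }
  w <- waveform(out, sample_rate)
  if (max(abs(w$samples)) > 1) w <- normalize_peak(w, 1) else w
}

#' Add a white-noise component to a harmonic source
#'
#' Mixes in white noise scaled so that `RMS(noise) / RMS(harmonic)` equals the
#' requested level in dB (the word experiment uses -30 dB). A level of `-Inf`
#' disables the noise entirely.
#'
#' @param harmonic A [waveform()] holding the harmonic component.
#' @param noise_level Noise level in dB relative to the harmonic RMS.
#' @return A [waveform()].
#' @export
add_source_noise <- function(harmonic, noise_level) {
  stopifnot(inherits(harmonic, "waveform"))
  if (is.na(noise_level)) stop("noise_level must not be NA")
  if (noise_level == -Inf) return(harmonic)
  h_rms <- rms(harmonic)
  if (h_rms == 0) {
    stop("cannot scale noise against a silent harmonic component")
  }
  noise <- stats::rnorm(length(harmonic$samples))
  noise <- noise / rms(noise) * h_rms * db_to_ratio(noise_level)
  waveform(harmonic$samples + noise, harmonic$sample_rate)
}

#' Aperiodic turbulent-noise source (whisper)
#'
#' The whisper condition replaces the harmonic source entirely with white
#' noise: no harmonic component, no pitch, no detectable spectral line
#' structure.
#'
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return A [waveform()] of Gaussian white noise, peak-normalized.
#' @export
whisper_source <- function(duration, sample_rate) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * sample_rate)
  normalize_peak(waveform(stats::rnorm(n), sample_rate))
}
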