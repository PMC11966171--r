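# Small shared fixtures, built once per test run.

SR <- 22050

tone <- function(freq, duration = 1, sr = SR, amp = 1) {
  waveform(amp * sin(2 * pi * freq * (seq_len(round(duration * sr)) - 1) / sr),
           sr)
}

constant_track <- function(f0, duration = 1, sr = SR) {
  rep(f0, round(duration * sr))
}

# dB level of harmonic k of a constant-f0 tone, relative to harmonic 1.
harmonic_level_db <- function(wave, f0, k) {
  sp <- measure_spectrum(wave)
  ratio_to_db(peak_level(sp, k * f0) / peak_level(sp, f0))
}

# Max normalized autocorrelation off lag zero within a pitch-lag range.
max_pitch_autocorr <- function(wave, f_lo = 30, f_hi = 3000) {
  x <- wave$samples - mean(wave$samples)
  n <- length(x)
  lag_min <- max(2L, floor(wave$sample_rate / f_hi))
  lag_max <- min(n - 1L, ceiling(wave$sample_rate / f_lo))
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  max(abs(ac[(lag_min + 1L):(lag_max + 1L)]))
}

small_exp1_manifest <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_exp1_manifest(42)
    cache
  }
})

shared_material <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_material(42)
    cache
  }
})
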