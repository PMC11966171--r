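#' Magnitude spectrum of a waveform
#'
#' Single Hann-windowed DFT of the whole signal, amplitude-calibrated so a
#' unit-amplitude sinusoid reads 1 at its frequency. Used throughout the
#' test suite to verify rolloff laws, sidebands and subharmonic peaks.
#'
#' @param wave A [waveform()].
#' @return A tibble with `freq_hz` and `amplitude` (linear).
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 220 * (0:22049) / 22050), 22050)
#' sp <- measure_spectrum(w)
#' sp$freq_hz[which.max(sp$amplitude)]
measure_spectrum <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  n <- length(x)
  w <- hann_window(n)
  X <- stats::fft(x * w)
  half <- floor(n / 2) + 1L
  amp <- 2 * Mod(X[seq_len(half)]) / sum(w)
  tibble::tibble(
    freq_hz = (seq_len(half) - 1) * wave$sample_rate / n,
    amplitude = amp
  )
}

#' Peak amplitude near a target frequency
#'
#' Maximum spectral amplitude within `tol_hz` of `freq_hz` — a tolerant
#' line-amplitude reader for verifying harmonic levels.
#'
#' @param spectrum Tibble from [measure_spectrum()].
#' @param freq_hz Target frequency in Hz.
#' @param tol_hz Search half-width in Hz (default 15).
#' @return Peak linear amplitude in the window.
#' @export
peak_level <- function(spectrum, freq_hz, tol_hz = 15) {
  sel <- abs(spectrum$freq_hz - freq_hz) <= tol_hz
  if (!any(sel)) stop("no spectral bins within tolerance of ", freq_hz, " Hz")
  max(spectrum$amplitude[sel])
}

#' Measure a noise spectrum against a flat-then-sloping profile
#'
#' Estimates the averaged (Welch-style) spectrum of a noise waveform,
#' smooths it, and summarizes: the maximum deviation from flatness below the
#' corner frequency and the fitted spectral slope (linear regression of dB on
#' kHz) above it.
#'
#' @param wave A [waveform()] of noise.
#' @param corner Corner frequency in Hz (default 1200).
#' @param n_fft STFT size for the averaged spectrum (default 1024).
#' @return A list: `slope_db_per_khz`, `flatness_db` (max |deviation| below
#'   the corner), and the smoothed `spectrum` tibble (`freq_hz`, `level_db`).
#' @export
measure_noise_profile <- function(wave, corner = 1200, n_fft = 1024L) {
  stopifnot(inherits(wave, "waveform"))
  S <- stft(wave$samples, wave$sample_rate, n_fft = n_fft)
  mag <- sqrt(rowMeans(Mod(S$frames)^2))
  level <- ratio_to_db(pmax(mag, 1e-12))
  level <- smooth_moving(level, 5)
  freqs <- S$freqs
  # skip DC/edge bins and the top of the band where the window leaks
  keep <- freqs > 50 & freqs < wave$sample_rate / 2 - 200
  below <- keep & freqs < corner * 0.9
  above <- keep & freqs > corner * 1.1
  flat_dev <- max(abs(level[below] - mean(level[below])))
  fit <- stats::lm(level[above] ~ I(freqs[above] / 1000))
  list(slope_db_per_khz = unname(stats::coef(fit)[2]),
       flatness_db = flat_dev,
       spectrum = tibble::tibble(freq_hz = freqs[keep],
                                 level_db = level[keep]))
}

#' Plot a waveform
#'
#' Oscillogram (amplitude against time), downsampled for display.
#'
#' @param object A [waveform()].
#' @param max_points Maximum points to draw (default 4000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.waveform <- function(object, max_points = 4000, ...) {
  n <- length(object$samples)
  idx <- unique(round(seq(1, n, length.out = min(n, max_points))))
  df <- tibble::tibble(time_s = (idx - 1) / object$sample_rate,
                       amplitude = object$samples[idx])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a magnitude spectrum in dB
#'
#' @param wave A [waveform()].
#' @param fmax Upper frequency limit in Hz (default Nyquist).
#' @param floor_db Display floor in dB (default -90).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(wave, fmax = NULL, floor_db = -90) {
  sp <- measure_spectrum(wave)
  if (is.null(fmax)) fmax <- wave$sample_rate / 2
  sp <- sp[sp$freq_hz <= fmax & sp$freq_hz > 0, ]
  sp$level_db <- pmax(ratio_to_db(pmax(sp$amplitude, 1e-12)), floor_db)
  ggplot2::ggplot(sp, ggplot2::aes(.data$freq_hz, .data$level_db)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frequency (Hz)", y = "level (dB)") +
    ggplot2::theme_minimal()
}
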