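#' Construct a waveform
#'
#' A waveform is the package's container for mono audio: a numeric sample
#' vector plus its sample rate. All synthesis and filtering functions take and
#' return waveforms.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq(0, 1, length.out = 22050)), 22050)
#' duration(w)
waveform <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.3f s @ %g Hz, peak %.3f, RMS %.4f>\n",
              duration(x), x$sample_rate, max(abs(x$samples)), rms(x)))
  invisible(x)
}

#' @rdname waveform
#' @param x A waveform.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "waveform"))
  length(x$samples) / x$sample_rate
}

#' Root-mean-square amplitude
#'
#' @param x A waveform or numeric vector.
#' @return RMS amplitude (linear scale).
#' @export
rms <- function(x) {
  if (inherits(x, "waveform")) x <- x$samples
  sqrt(mean(x^2))
}

#' Decibel conversions
#'
#' `db_to_ratio()` converts a level in dB to a linear amplitude ratio
#' (20 dB per decade); `ratio_to_db()` is its inverse.
#'
#' @param db Level in dB.
#' @param ratio Linear amplitude ratio (> 0).
#' @return Numeric vector.
#' @export
db_to_ratio <- function(db) 10^(db / 20)

#' @rdname db_to_ratio
#' @export
ratio_to_db <- function(ratio) 20 * log10(ratio)

#' Peak-normalize a waveform
#'
#' Scales the waveform so that max |amplitude| equals `peak`.
#'
#' @param x A waveform.
#' @param peak Target peak amplitude (default 0.95, headroom for 16-bit PCM).
#' @return A waveform.
#' @export
normalize_peak <- function(x, peak = 0.95) {
  stopifnot(inherits(x, "waveform"))
  m <- max(abs(x$samples))
  if (m == 0) return(x)
  waveform(x$samples * (peak / m), x$sample_rate)
}

# Analytic-signal magnitude via FFT: zero the negative frequencies, double the
# positive ones, back-transform; |result| is the instantaneous envelope.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Centered moving average with reflected edges; window in samples.
smooth_moving <- function(x, window) {
  window <- max(1L, as.integer(round(window)))
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2
  padded <- c(rev(x[seq_len(min(half, n))]), x,
              rev(x[seq.int(n, by = -1, length.out = min(half, n))]))
  k <- rep(1 / window, window)
  sm <- stats::filter(padded, k, sides = 2)
  out <- as.numeric(sm[(half + 1):(half + n)])
  # edge NAs can remain when the pad is shorter than half the window
  out[is.na(out)] <- x[is.na(out)]
  out
}

#' Write a waveform as a WAV file
#'
#' Mono 16-bit PCM. Samples are clipped to \[-1, 1\] before quantization.
#'
#' @param x A waveform.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "waveform"))
  s <- pmax(pmin(x$samples, 1), -1)
  pcm <- as.integer(round(s * 32767))
  sr <- as.integer(round(x$sample_rate))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path Path to a WAV file written by [write_wav()] or any mono
#'   16-bit PCM WAV.
#' @return A waveform with samples in \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (bits[2] != 16L) stop("only 16-bit WAV supported")
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little",
                     signed = TRUE)
      if (is.null(sr)) stop("data chunk precedes fmt chunk in ", path)
      return(waveform(pcm / 32767, sr))
    } else {
      readBin(con, "raw", size)
    }
  }
}

# ---- Short-time Fourier transform ------------------------------------------
# Hann-windowed STFT with hop = n_fft/4 (COLA-compliant), plus inverse by
# weighted overlap-add. Internal: the envelope machinery is built on these.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Number of STFT frames stft() produces for an n-sample signal.
n_stft_frames <- function(n, n_fft = 1024L, hop = n_fft %/% 4L) {
  max(1L, as.integer(ceiling(max(0L, n - n_fft) / hop)) + 1L)
}

stft <- function(x, sample_rate, n_fft = 1024L, hop = n_fft %/% 4L) {
  n <- length(x)
  n_frames <- max(1L, as.integer(ceiling(max(0L, n - n_fft) / hop)) + 1L)
  pad_to <- (n_frames - 1L) * hop + n_fft
  if (length(x) < pad_to) x <- c(x, numeric(pad_to - length(x)))
  w <- hann_window(n_fft)
  starts <- seq.int(1L, by = hop, length.out = n_frames)
  frames <- vapply(starts, function(s) {
    stats::fft(x[s:(s + n_fft - 1L)] * w)[1:(n_fft %/% 2L + 1L)]
  }, complex(n_fft %/% 2L + 1L))
  list(frames = frames, n_fft = n_fft, hop = hop, n_samples = n,
       sample_rate = sample_rate,
       freqs = seq(0, sample_rate / 2, length.out = n_fft %/% 2L + 1L),
       times = (starts - 1L + n_fft / 2) / sample_rate)
}

istft <- function(S) {
  n_fft <- S$n_fft
  hop <- S$hop
  w <- hann_window(n_fft)
  n_frames <- ncol(S$frames)
  out_len <- (n_frames - 1L) * hop + n_fft
  y <- numeric(out_len)
  wsum <- numeric(out_len)
  for (j in seq_len(n_frames)) {
    half <- S$frames[, j]
    full <- c(half, Conj(rev(half[2:(length(half) - 1L)])))
    frame <- Re(stats::fft(full, inverse = TRUE)) / n_fft
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + n_fft)
    y[idx] <- y[idx] + frame * w
    wsum[idx] <- wsum[idx] + w^2
  }
  y <- y / pmax(wsum, 1e-8)
  y[seq_len(S$n_samples)]
}
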