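#' Episode windows for intermittent manipulations
#'
#' Nonlinear-phonation effects are applied either to a whole stimulus
#' (continuous) or in several stochastic episodes (intermittent). Episodes are
#' represented as a tibble of `(start, end)` fractions of total duration,
#' non-overlapping and ascending. `episodes_continuous()` is the single
#' window `[0, 1]`.
#'
#' @param start,end Numeric vectors of window edges as fractions in \[0, 1\].
#' @return A tibble with columns `start`, `end`.
#' @export
episodes <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(start < 0 | end > 1 | start >= end)) {
    stop("episode windows must satisfy 0 <= start < end <= 1")
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)])) {
    stop("episode windows must not overlap")
  }
  tibble::tibble(start = start, end = end)
}

#' @rdname episodes
#' @export
episodes_continuous <- function() episodes(0, 1)

# Per-sample gating mask in [0, 1] for a set of episode windows, with
# raised-cosine ramps at the edges (default 5 ms) so nothing clicks.
episode_mask <- function(n, eps, sample_rate, ramp_s = 0.005) {
  mask <- numeric(n)
  ramp_n <- round(ramp_s * sample_rate)
  up <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / (ramp_n + 1))  # 0 -> 1
  for (i in seq_len(nrow(eps))) {
    a <- max(1L, floor(eps$start[i] * n) + 1L)
    b <- min(n, ceiling(eps$end[i] * n))
    win <- rep(1, b - a + 1L)
    if (ramp_n > 0L && length(win) > 2L * ramp_n) {
      if (a > 1L) win[seq_len(ramp_n)] <- up
      if (b < n) win[seq.int(length(win), by = -1L, length.out = ramp_n)] <- up
    }
    mask[a:b] <- pmax(mask[a:b], win)
  }
  mask
}

#' Amplitude modulation at the source level
#'
#' Within the episode windows, samples are multiplied by
#' `1 - depth/2 + (depth/2) * cos(2*pi*freq*t)`: `depth` is the peak-to-trough
#' modulation as a fraction of the mean level, so sidebands appear at the
#' carrier +/- `freq` with amplitude `depth/4` relative to the carrier.
#' The vowel experiment draws `freq` in 50-150 Hz and `depth` in 0.4-0.6; the
#' word experiment uses depths of 0.3-0.6.
#'
#' @param wave A [waveform()].
#' @param freq Modulation frequency in Hz.
#' @param depth Modulation depth in \[0, 1\].
#' @param episodes Episode windows from [episodes()]; default continuous.
#' @return A modulated [waveform()].
#' @export
apply_am <- function(wave, freq, depth, episodes = episodes_continuous()) {
  stopifnot(inherits(wave, "waveform"))
  if (depth < 0 || depth > 1) stop("AM depth must lie in [0, 1]")
  if (freq >= wave$sample_rate / 2) {
    stop("AM frequency must be below Nyquist")
  }
  if (depth == 0) return(wave)
  n <- length(wave$samples)
  t <- (seq_len(n) - 1) / wave$sample_rate
  gain <- 1 - depth / 2 + (depth / 2) * cos(2 * pi * freq * t)
  mask <- episode_mask(n, episodes, wave$sample_rate)
  waveform(wave$samples * (1 + mask * (gain - 1)), wave$sample_rate)
}

#' Add subharmonics (period doubling) to a harmonic source
#'
#' Inserts additional partials at `m * f0 / ratio` for every integer `m` not
#' divisible by `ratio` (for the classic period doubling, `ratio = 2`:
#' partials at f0/2, 3f0/2, 5f0/2, ...), each with amplitude `depth` times
#' the rolloff-implied amplitude at that frequency. The waveform period
#' becomes `ratio / f0`. Episodes gate the subharmonic component only; the
#' ordinary harmonics are untouched.
#'
#' @param f0_track Per-sample f0 in Hz (`NA` = unvoiced).
#' @param rolloff Spectral rolloff in dB/octave used for the harmonic stack.
#' @param sample_rate Sampling rate in Hz.
#' @param ratio Integer subharmonic divisor >= 2 (2 = period doubling at
#'   f0/2, as used throughout the experiments).
#' @param depth Subharmonic depth in \[0, 1\] (0.4-0.6 in the vowel
#'   experiment, 0.3-0.5 in the word experiment).
#' @param episodes Episode windows; default continuous.
#' @return A [waveform()] containing harmonics plus gated subharmonics.
#' @export
apply_subharmonics <- function(f0_track, rolloff, sample_rate, ratio = 2L,
                               depth = 0.5,
                               episodes = episodes_continuous()) {
  ratio <- as.integer(ratio)
  if (ratio < 2L) stop("subharmonic ratio must be an integer >= 2")
  if (depth < 0 || depth > 1) stop("subharmonic depth must lie in [0, 1]")
  voiced <- !is.na(f0_track)
  if (any(voiced) && min(f0_track[voiced]) / ratio < 20) {
    stop("subharmonic would fall below 20 Hz")
  }
  if (depth == 0) return(synth_harmonics(f0_track, rolloff, sample_rate))
  nyquist <- sample_rate / 2
  f0_max <- max(f0_track[voiced])
  k_max <- floor((nyquist - 50) / f0_max)
  if (k_max < 1L) stop("no harmonic fits below Nyquist minus the guard band")
  harm <- tibble::tibble(
    ratio = as.numeric(seq_len(k_max)),
    amp = db_to_ratio(-rolloff * log2(seq_len(k_max)))
  )
  m_all <- seq_len(floor((nyquist - 50) * ratio / f0_max))
  m_sub <- m_all[m_all %% ratio != 0L]
  sub_ratios <- m_sub / ratio
  subs <- tibble::tibble(
    ratio = sub_ratios,
    amp = depth * db_to_ratio(-rolloff * log2(sub_ratios))
  )
  # harmonic stack and gated subharmonic partials share one raw amplitude
  # scale (harmonic 1 = 1) and one phase base; normalize only at the end
  harm_raw <- synth_partials(f0_track, harm, sample_rate)
  sub_raw <- synth_partials(f0_track, subs, sample_rate)
  mask <- episode_mask(length(harm_raw), episodes, sample_rate)
  w <- waveform(harm_raw + mask * sub_raw, sample_rate)
  if (max(abs(w$samples)) > 1) normalize_peak(w, 1) else w
}

# Additive synthesis of arbitrary partials (frequency = ratio * f0), phase
# accumulated from the f0 track. Returns a bare sample vector on the scale of
# harmonic 1 = amplitude 1.
synth_partials <- function(f0_track, partials, sample_rate) {
  voiced <- !is.na(f0_track)
  f0_filled <- f0_track
  f0_filled[!voiced] <- 0
  phase_base <- 2 * pi * cumsum(f0_filled) / sample_rate
  out <- numeric(length(f0_track))
  for (i in seq_len(nrow(partials))) {
    out <- out + partials$amp[i] * sin(partials$ratio[i] * phase_base)
  }
  out[!voiced] <- 0
  out
}

#' Rapid jitter as an imitation of deterministic chaos
#'
#' Multiplies the f0 track by `2^(u(t)/12)` where `u(t)` is zero-mean noise,
#' uniform in `[-depth/2, +depth/2]` semitones, resampled at `rate` Hz with
#' linear interpolation between update points (sample-and-hold available via
#' `interpolation = "constant"`). The perturbation never exceeds `depth/2`
#' semitones in absolute value. The vowel experiment uses depth 2-4 st at
#' 1 kHz; the word experiment depths of 1-4 st.
#'
#' @param f0_track Per-sample f0 in Hz (`NA` = unvoiced).
#' @param depth Total jitter depth in semitones (>= 0).
#' @param rate Update rate of the jitter noise in Hz (1000 Hz in the
#'   experiments).
#' @param sample_rate Sampling rate of the track in Hz.
#' @param episodes Episode windows; default continuous.
#' @param interpolation `"linear"` (default) or `"constant"` between jitter
#'   update points.
#' @return A perturbed per-sample f0 track.
#' @export
apply_jitter <- function(f0_track, depth, rate, sample_rate,
                         episodes = episodes_continuous(),
                         interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  if (depth < 0) stop("jitter depth must be >= 0")
  if (rate > sample_rate / 2) stop("jitter rate must be <= sample_rate / 2")
  if (depth == 0) return(f0_track)
  n <- length(f0_track)
  step <- sample_rate / rate
  pts <- seq(1, n + step, by = step)
  u_pts <- stats::runif(length(pts), -depth / 2, depth / 2)
  u <- stats::approx(pts, u_pts, xout = seq_len(n),
                     method = interpolation, rule = 2)$y
  mask <- episode_mask(n, episodes, sample_rate)
  f0_track * 2^((u * mask) / 12)
}

#' Plan alternating frequency jumps across a sentence
#'
#' Draws `n_jumps` jump specifications (time as a fraction of duration,
#' magnitude in semitones, direction), placing jumps inside voiced spans and
#' favouring alternation: each jump opposes the previous one with probability
#' `p_alternate`, and a jump that would carry the running shift outside
#' `[-12, +12]` semitones is forced to oppose it. This keeps the cumulative
#' excursion small, so the manipulated contour stays within an octave of the
#' original range. Sentence stimuli use about five jumps of 0.5-12 st each.
#'
#' @param contour An [f0_contour()] spanning the sentence.
#' @param n_jumps Number of jumps (>= 1; around 5 per sentence).
#' @param magnitude_range Semitone range to draw magnitudes from, default
#'   `c(0.5, 12)`.
#' @param p_alternate Probability that a jump opposes the previous one
#'   (default 0.9, at least 0.8 by design).
#' @return A tibble with columns `point` (fraction), `magnitude` (st),
#'   `direction` (`"up"`/`"down"`), ordered by `point`.
#' @export
plan_jumps_alternating <- function(contour, n_jumps = 5,
                                   magnitude_range = c(0.5, 12),
                                   p_alternate = 0.9) {
  validate_f0_contour(contour)
  if (n_jumps < 1) stop("need at least one jump")
  spans <- voiced_spans(contour)
  t0 <- min(contour$time_s)
  t1 <- max(contour$time_s)
  total <- t1 - t0
  windows <- purrr::keep(spans, function(r) {
    diff(range(contour$time_s[r])) > 0.02 * total
  })
  if (length(windows) == 0L) stop("no voiced span long enough to place jumps")
  pts <- sort(purrr::map_dbl(seq_len(n_jumps), function(i) {
    r <- windows[[sample.int(length(windows), 1)]]
    lo <- min(contour$time_s[r])
    hi <- max(contour$time_s[r])
    stats::runif(1, lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))
  }))
  mags <- stats::runif(n_jumps, magnitude_range[1], magnitude_range[2])
  dirs <- character(n_jumps)
  cum <- 0
  for (i in seq_len(n_jumps)) {
    if (i == 1L) {
      dirs[i] <- sample(c("up", "down"), 1)
    } else {
      opposite <- if (dirs[i - 1] == "up") "down" else "up"
      dirs[i] <- if (stats::runif(1) < p_alternate) opposite else dirs[i - 1]
    }
    delta <- if (dirs[i] == "up") mags[i] else -mags[i]
    if (abs(cum + delta) > 12) {  # would drift out of +/- one octave
      dirs[i] <- if (cum + delta > 0) "down" else "up"
      delta <- if (dirs[i] == "up") mags[i] else -mags[i]
    }
    cum <- cum + delta
  }
  tibble::tibble(point = (pts - t0) / total, magnitude = mags,
                 direction = dirs)
}

#' Apply a plan of frequency jumps to a contour
#'
#' Applies each jump from [plan_jumps_alternating()] in time order via
#' [apply_frequency_jump()]; shifts accumulate, so alternation keeps the
#' contour near its original register.
#'
#' @param contour An [f0_contour()].
#' @param plan A tibble with `point`, `magnitude`, `direction` columns.
#' @return The jumped `f0_contour`.
#' @export
apply_jump_plan <- function(contour, plan) {
  for (i in order(plan$point)) {
    contour <- apply_frequency_jump(contour, plan$point[i],
                                    plan$magnitude[i], plan$direction[i])
  }
  contour
}

#' Draw episode windows for a stimulus
#'
#' Continuous mode returns the single window `[0, 1]`. Intermittent mode
#' draws the episode count from a Poisson(5) truncated to \[2, 8\] and places
#' that many non-overlapping windows with total coverage between 20% and 80%
#' of the stimulus ("about five separate episodes per sentence").
#'
#' @param duration Stimulus duration in seconds (> 0).
#' @param mode `"continuous"` or `"intermittent"`.
#' @param n_mean Mean of the truncated Poisson episode count (default 5).
#' @return An [episodes()] tibble.
#' @export
place_episodes <- function(duration, mode = c("continuous", "intermittent"),
                           n_mean = 5) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be positive")
  if (mode == "continuous") return(episodes_continuous())
  n <- 0L
  while (n < 2L || n > 8L) n <- stats::rpois(1, n_mean)
  coverage <- stats::runif(1, 0.2, 0.8)
  # split the covered fraction into n windows and spread them over the gaps
  w <- stats::runif(n, 0.5, 1.5)
  w <- w / sum(w) * coverage
  g <- stats::runif(n + 1, 0.5, 1.5)
  g <- g / sum(g) * (1 - coverage)
  starts <- cumsum(g)[seq_len(n)] + c(0, cumsum(w))[seq_len(n)]
  episodes(starts, starts + w)
}
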