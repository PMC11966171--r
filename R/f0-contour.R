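#' Construct a fundamental-frequency contour
#'
#' An f0 contour is a tibble of time-stamped pitch anchors: the substrate of
#' every source manipulation. Anchors in voiced spans carry a frequency in Hz;
#' contiguous runs of `voiced = TRUE` anchors define voiced spans, the rest is
#' treated as unvoiced (silence at source level).
#'
#' @param times Anchor times in seconds, strictly increasing.
#' @param values f0 values in Hz. Voiced values must lie in (30, 3000) Hz.
#' @param voiced Logical vector, one flag per anchor (default all `TRUE`).
#' @return A tibble of class `f0_contour` with columns `time_s`, `f0_hz`,
#'   `voiced`.
#' @export
#' @examples
#' f0_contour(c(0, 0.7), c(110, 220))
f0_contour <- function(times, values, voiced = rep(TRUE, length(times))) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  voiced <- as.logical(voiced)
  if (length(times) == 0L) stop("f0 contour must have at least one anchor")
  if (length(values) != length(times) || length(voiced) != length(times)) {
    stop("times, values and voiced must have equal length")
  }
  if (any(diff(times) <= 0)) stop("anchor times must be strictly increasing")
  if (any(voiced & (values <= 30 | values >= 3000))) {
    stop("voiced f0 values must lie in (30, 3000) Hz")
  }
  if (sum(voiced) == 1L) {
    stop("a voiced segment needs at least 2 anchors")
  }
  out <- tibble::tibble(time_s = times, f0_hz = values, voiced = voiced)
  class(out) <- c("f0_contour", class(out))
  out
}

validate_f0_contour <- function(contour) {
  if (!is.data.frame(contour) ||
      !all(c("time_s", "f0_hz", "voiced") %in% names(contour))) {
    stop("expected an f0_contour (columns time_s, f0_hz, voiced)")
  }
  if (nrow(contour) == 0L) stop("empty f0 contour")
  if (any(diff(contour$time_s) <= 0)) {
    stop("anchor times must be strictly increasing")
  }
  invisible(contour)
}

#' Interpolate an f0 contour to a per-sample pitch track
#'
#' Anchors are interpolated on a log-frequency grid with a monotone cubic
#' (Fritsch-Carlson) spline, giving smooth contours with continuous first
#' differences inside voiced spans and no overshoot between anchors. Unvoiced
#' spans are marked `NA` in the returned track.
#'
#' @param contour An [f0_contour()].
#' @param sample_rate Target sampling rate in Hz (22 050 Hz throughout the
#'   experiments).
#' @param duration Optional duration in seconds; defaults to the last anchor
#'   time. The track is held at the edge anchor values beyond the anchor span.
#' @return Numeric vector of f0 values (Hz), one per sample; `NA` where
#'   unvoiced.
#' @export
#' @examples
#' tr <- interpolate_f0(f0_contour(c(0, 1), c(110, 220)), 22050)
#' range(tr)
interpolate_f0 <- function(contour, sample_rate, duration = NULL) {
  validate_f0_contour(contour)
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(duration)) duration <- max(contour$time_s)
  if (duration <= 0) stop("duration must be positive")
  n <- max(1L, round(duration * sample_rate))
  t_grid <- (seq_len(n) - 1) / sample_rate
  track <- rep(NA_real_, n)
  runs <- voiced_spans(contour)
  for (r in runs) {
    seg <- contour[r, ]
    # split at abrupt discontinuities (anchor pairs < 1 ms apart, e.g. from
    # frequency jumps) so the spline never smooths — or overshoots — across
    pieces <- split_at_jumps(seg)
    for (piece in pieces) {
      lo <- min(piece$time_s)
      hi <- max(piece$time_s)
      idx <- which(t_grid >= lo & t_grid <= hi)
      if (length(idx) == 0L) next
      if (nrow(piece) == 1L || max(piece$f0_hz) == min(piece$f0_hz)) {
        track[idx] <- piece$f0_hz[1]
      } else {
        f <- stats::splinefun(piece$time_s, log(piece$f0_hz),
                              method = "monoH.FC")
        track[idx] <- exp(f(t_grid[idx]))
      }
    }
  }
  # fill isolated NA samples that fall inside the hair-width gap a jump
  # discontinuity leaves between interpolation pieces
  nas <- which(is.na(track))
  if (length(nas) > 0L && length(nas) < n) {
    runs <- split(nas, cumsum(c(1L, diff(nas) != 1L)))
    for (run in runs) {
      if (length(run) > 4L) next
      left <- min(run) - 1L
      right <- max(run) + 1L
      if (left >= 1L && right <= n && !is.na(track[left]) &&
          !is.na(track[right])) {
        track[run] <- ifelse(run - left <= right - run, track[left],
                             track[right])
      }
    }
  }
  # a fully voiced contour extends to the requested duration at edge values
  if (all(contour$voiced)) {
    track[t_grid < contour$time_s[1]] <- contour$f0_hz[1]
    track[t_grid > max(contour$time_s)] <- contour$f0_hz[nrow(contour)]
  }
  track
}

# Split a voiced segment into pieces at discontinuities: anchor pairs closer
# than `gap` seconds mark an intentional step in the contour.
split_at_jumps <- function(seg, gap = 1e-3) {
  cuts <- which(diff(seg$time_s) < gap)
  if (length(cuts) == 0L) return(list(seg))
  bounds <- c(0L, cuts, nrow(seg))
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    piece <- seg[(bounds[b] + 1L):bounds[b + 1L], , drop = FALSE]
    if (nrow(piece) > 0L) out[[length(out) + 1L]] <- piece
  }
  out
}

# Indices of contiguous voiced anchor runs, as a list of integer vectors.
voiced_spans <- function(contour) {
  v <- contour$voiced
  if (!any(v)) return(list())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) starts[i]:ends[i])
}

#' Shift an f0 contour by whole or fractional octaves
#'
#' Multiplies every f0 value by `2^octaves`, preserving the contour shape
#' exactly in the log domain. The experiments use upward shifts of 0, 1 or
#' 1.5 octaves (never for whispered stimuli, which carry no f0).
#'
#' @param contour An [f0_contour()].
#' @param octaves Shift in octaves; positive = upward.
#' @return A shifted `f0_contour`.
#' @export
#' @examples
#' apply_pitch_shift(f0_contour(c(0, 1), c(220, 220)), 1)$f0_hz
apply_pitch_shift <- function(contour, octaves) {
  validate_f0_contour(contour)
  stopifnot(is.numeric(octaves), length(octaves) == 1L, is.finite(octaves))
  shifted <- contour$f0_hz * 2^octaves
  if (any(contour$voiced & shifted > 3000)) {
    stop("pitch shift would push f0 above 3000 Hz")
  }
  f0_contour(contour$time_s, shifted, contour$voiced)
}

#' Insert an abrupt frequency jump into an f0 contour
#'
#' All anchors after the discontinuity point are shifted by the given number
#' of semitones; an anchor pair is inserted at the discontinuity so that no
#' smoothing occurs across the jump. In the word experiment the point is
#' drawn between 25% and 75% of each token's duration and the magnitude
#' between 3 and 12 semitones, either direction.
#'
#' @param contour An [f0_contour()].
#' @param point Jump location as a fraction of total duration, in (0, 1).
#' @param magnitude Jump size in semitones (>= 0).
#' @param direction `"up"` or `"down"`.
#' @return An `f0_contour` with the discontinuity inserted.
#' @export
#' @examples
#' apply_frequency_jump(f0_contour(c(0, 1), c(220, 220)), 0.5, 12, "up")
apply_frequency_jump <- function(contour, point, magnitude,
                                 direction = c("up", "down")) {
  validate_f0_contour(contour)
  direction <- match.arg(direction)
  if (!is.numeric(point) || point <= 0 || point >= 1) {
    stop("jump point must lie strictly inside (0, 1)")
  }
  if (magnitude < 0) stop("jump magnitude must be >= 0")
  if (magnitude == 0) return(contour)
  sign <- if (direction == "up") 1 else -1
  ratio <- 2^(sign * magnitude / 12)
  t0 <- min(contour$time_s)
  t1 <- max(contour$time_s)
  t_jump <- t0 + point * (t1 - t0)
  eps <- (t1 - t0) * 1e-6
  pre <- contour[contour$time_s < t_jump, , drop = FALSE]
  post <- contour[contour$time_s >= t_jump, , drop = FALSE]
  # value at the discontinuity on each side, so the step is exactly `ratio`
  f <- stats::approxfun(contour$time_s, contour$f0_hz, rule = 2)
  v <- stats::approxfun(contour$time_s, as.numeric(contour$voiced),
                        method = "constant", rule = 2)
  at_jump <- f(t_jump)
  voiced_at <- v(t_jump) > 0.5
  times <- c(pre$time_s, t_jump - eps, t_jump + eps, post$time_s + 2 * eps)
  values <- c(pre$f0_hz, at_jump, at_jump * ratio, post$f0_hz * ratio)
  voiced <- c(pre$voiced, voiced_at, voiced_at, post$voiced)
  if (any(voiced & values >= 3000)) {
    stop("frequency jump would push f0 to 3000 Hz or above")
  }
  if (any(voiced & values <= 30)) {
    stop("frequency jump would push f0 to 30 Hz or below")
  }
  f0_contour(times, values, voiced)
}

#' Read or write an f0 contour as CSV
#'
#' The on-disk schema is `time_s, f0_hz, voiced` — one row per anchor.
#'
#' @param contour An [f0_contour()].
#' @param path File path.
#' @return `write_f0_csv()` returns `path` invisibly; `read_f0_csv()` returns
#'   an `f0_contour`.
#' @export
write_f0_csv <- function(contour, path) {
  validate_f0_contour(contour)
  utils::write.csv(as.data.frame(contour), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_f0_csv
#' @export
read_f0_csv <- function(path) {
  df <- utils::read.csv(path)
  f0_contour(df$time_s, df$f0_hz, as.logical(df$voiced))
}
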