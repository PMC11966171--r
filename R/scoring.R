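#' Normalize a free-text transcription
#'
#' Lower-cases the text, removes every character that is not alphanumeric or
#' a space, collapses runs of whitespace to single spaces and trims the ends.
#' Idempotent; empty input gives an empty string.
#'
#' @param text Character vector of raw responses.
#' @return Character vector of canonical responses.
#' @export
#' @examples
#' normalize_response("The  Jacket, hung!")
normalize_response <- function(text) {
  text <- tolower(as.character(text))
  text <- stringr::str_replace_all(text, "[^a-z0-9 ]", " ")
  text <- stringr::str_squish(text)
  text
}

#' Count positional digit errors against a six-digit target
#'
#' Compares the response with the target digit-by-digit; positions beyond the
#' end of a short response count as errors, as do extra response digits beyond
#' position six (they cannot match anything). Result ranges 0/6 to 6/6.
#'
#' @param target A string of exactly 6 digits.
#' @param response A string of digits (any length after normalization).
#' @return Integer error count in 0..6.
#' @export
#' @examples
#' digit_match("123456", "123455")
digit_match <- function(target, response) {
  target <- gsub(" ", "", normalize_response(target))
  response <- gsub(" ", "", normalize_response(response))
  if (!grepl("^[0-9]{6}$", target)) stop("target must be exactly 6 digits")
  if (!grepl("^[0-9]*$", response)) {
    stop("response contains non-digit characters")
  }
  tgt <- strsplit(target, "")[[1]]
  rsp <- strsplit(response, "")[[1]]
  errors <- 0L
  for (i in 1:6) {
    if (i > length(rsp) || rsp[i] != tgt[i]) errors <- errors + 1L
  }
  errors
}

#' Symbol-level dynamic time warping distance
#'
#' Aligns the two symbol sequences with DTW using a 0/1 local cost (0 when
#' symbols match, 1 otherwise) and steps (i-1,j), (i,j-1), (i-1,j-1), and
#' returns the minimum alignment cost divided by the warping-path length
#' (among minimum-cost paths, the shortest). DTW penalizes substitutions and
#' inversions more than pure insertions or deletions, which stretch the path
#' instead of accumulating cost.
#'
#' @param target,response Non-empty character vectors of symbols, or single
#'   strings that are split into characters.
#' @return Normalized distance >= 0 (0 iff the sequences are identical).
#' @export
#' @examples
#' dtw_sequence_distance("123456", "123455")
dtw_sequence_distance <- function(target, response) {
  a <- as_symbols(target)
  b <- as_symbols(response)
  if (length(a) == 0L || length(b) == 0L) {
    stop("sequences must be non-empty")
  }
  n <- length(a)
  m <- length(b)
  cost <- matrix(Inf, n + 1L, m + 1L)
  plen <- matrix(Inf, n + 1L, m + 1L)
  cost[1, 1] <- 0
  plen[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      local <- if (a[i] == b[j]) 0 else 1
      cands_cost <- c(cost[i, j], cost[i, j + 1L], cost[i + 1L, j]) + local
      cands_len <- c(plen[i, j], plen[i, j + 1L], plen[i + 1L, j]) + 1
      best <- min(cands_cost)
      cost[i + 1L, j + 1L] <- best
      plen[i + 1L, j + 1L] <- min(cands_len[cands_cost == best])
    }
  }
  cost[n + 1L, m + 1L] / plen[n + 1L, m + 1L]
}

as_symbols <- function(x) {
  if (length(x) == 1L && is.character(x)) strsplit(x, "")[[1]] else as.character(x)
}

# Generic edit (Levenshtein) distance between two symbol vectors, unit costs.
edit_distance <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1,          # deletion
                         cur[j] + 1,                # insertion
                         prev[j] + (a[i] != b[j]))  # substitution
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Word error rate
#'
#' Word-level edit distance (substitutions + insertions + deletions) divided
#' by the number of words in the target, clamped to \[0, 1\] so that accuracy
#' `1 - WER` stays in \[0, 1\] even for insertion-heavy responses.
#'
#' @param target,response Normalized sentences (see [normalize_response()]).
#' @return WER in \[0, 1\].
#' @export
#' @examples
#' wer("an abrupt start does not win the prize",
#'     "an abrupt start does not win a prize")
wer <- function(target, response) {
  tw <- strsplit(stringr::str_squish(target), " ")[[1]]
  tw <- tw[tw != ""]
  if (length(tw) == 0L) stop("target sentence must be non-empty")
  rw <- strsplit(stringr::str_squish(response), " ")[[1]]
  rw <- rw[rw != ""]
  min(1, edit_distance(tw, rw) / length(tw))
}

#' Normalized Levenshtein distance
#'
#' Character-level edit distance divided by the number of characters in the
#' target. Can exceed 1 for long insertion-heavy responses.
#'
#' @param target,response Strings; the target must be non-empty.
#' @return Normalized distance >= 0.
#' @export
#' @examples
#' levenshtein_norm("kitten", "sitting")
levenshtein_norm <- function(target, response) {
  if (nchar(target) == 0L) stop("target must be non-empty")
  edit_distance(strsplit(target, "")[[1]], strsplit(response, "")[[1]]) /
    nchar(target)
}

#' Jaro distance
#'
#' One minus the Jaro similarity, computed with the standard matching window
#' `floor(max(|a|, |b|) / 2) - 1` and half-transposition counting. Focuses on
#' matching characters and tolerates transpositions.
#'
#' @param target,response Strings.
#' @return Distance in \[0, 1\] (0 for identical strings, 1 when no
#'   characters match).
#' @export
#' @examples
#' jaro_distance("martha", "marhta")
jaro_distance <- function(target, response) {
  a <- strsplit(target, "")[[1]]
  b <- strsplit(response, "")[[1]]
  if (length(a) == 0L && length(b) == 0L) return(0)
  if (length(a) == 0L || length(b) == 0L) return(1)
  win <- max(floor(max(length(a), length(b)) / 2) - 1, 0)
  b_used <- logical(length(b))
  a_match <- integer(0)
  b_match_pos <- integer(0)
  for (i in seq_along(a)) {
    lo <- max(1L, i - win)
    hi <- min(length(b), i + win)
    for (j in seq.int(lo, length.out = max(0L, hi - lo + 1L))) {
      if (!b_used[j] && a[i] == b[j]) {
        b_used[j] <- TRUE
        a_match <- c(a_match, i)
        b_match_pos <- c(b_match_pos, j)
        break
      }
    }
  }
  m <- length(a_match)
  if (m == 0L) return(1)
  t_half <- sum(a[a_match] != b[sort(b_match_pos)]) / 2
  sim <- (m / length(a) + m / length(b) + (m - t_half) / m) / 3
  1 - sim
}

#' Adjust response time for stimulus duration
#'
#' Subtracts the stimulus duration from the raw trial response time, removing
#' the variability due to sequence length; negative values are legitimate
#' (participants may answer while the stimulus is still playing).
#'
#' @param rt Raw response time in seconds (> 0).
#' @param duration Stimulus duration in seconds.
#' @return Adjusted response time in seconds.
#' @export
#' @examples
#' adjust_rt(6.3, 3.6)
adjust_rt <- function(rt, duration) {
  if (any(rt <= 0, na.rm = TRUE)) stop("response times must be positive")
  rt - duration
}

#' Score a table of listener responses against a manifest
#'
#' Joins responses to their stimulus records and computes per-trial
#' intelligibility metrics appropriate to the experiment: the binary response
#' itself for the vowel experiment, digit errors and DTW distance for the
#' word experiment, and WER / normalized Levenshtein / Jaro for the sentence
#' experiment (plus adjusted RT whenever `rt_s` and `duration_s` are
#' available).
#'
#' @param responses Tibble with `stimulus_id`, `subject_id`, `response` and
#'   optionally `rt_s`.
#' @param manifest A manifest tibble from [build_exp1_manifest()],
#'   [build_exp2_manifest()] or [build_exp3_manifest()].
#' @return The joined tibble with per-trial metric columns appended.
#' @export
score_responses <- function(responses, manifest) {
  exp_id <- unique(manifest$experiment)
  if (length(exp_id) != 1L) stop("manifest must come from a single experiment")
  if (!all(responses$stimulus_id %in% manifest$stimulus_id)) {
    stop("some responses reference stimuli missing from the manifest")
  }
  joined <- dplyr::inner_join(responses, manifest, by = "stimulus_id")
  if (exp_id == 1) {
    joined <- dplyr::mutate(joined, diphthong_response = as.integer(.data$response))
  } else if (exp_id == 2) {
    joined <- joined |>
      dplyr::mutate(
        digit_errors = purrr::map2_int(.data$digits, .data$response,
                                       digit_match),
        dtw_distance = purrr::map2_dbl(.data$digits, .data$response,
                                       function(t, r) {
                                         if (nchar(r) == 0) 1 else
                                           dtw_sequence_distance(t, r)
                                       })
      )
  } else {
    joined <- joined |>
      dplyr::mutate(
        response_norm = normalize_response(.data$response),
        target_norm = normalize_response(.data$text),
        wer = purrr::map2_dbl(.data$target_norm, .data$response_norm, wer),
        accuracy = 1 - .data$wer,
        levenshtein = purrr::map2_dbl(.data$target_norm, .data$response_norm,
                                      levenshtein_norm),
        jaro = purrr::map2_dbl(.data$target_norm, .data$response_norm,
                               jaro_distance)
      )
  }
  if (all(c("rt_s", "duration_s") %in% names(joined))) {
    joined <- dplyr::mutate(joined,
                            rt_adj_s = adjust_rt(.data$rt_s, .data$duration_s))
  }
  joined
}
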