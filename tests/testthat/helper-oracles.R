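# Independent oracles for the string metrics. These deliberately avoid the
# package's own code paths: Levenshtein / word-level edit distance go through
# utils::adist, Jaro through a second from-scratch routine, and DTW through
# brute-force enumeration of every monotone warping path.

oracle_levenshtein <- function(a, b) {
  drop(utils::adist(a, b))
}

# Word-level edit distance via adist on a one-character-per-word recoding.
oracle_word_edit <- function(target_words, response_words) {
  vocab <- unique(c(target_words, response_words))
  if (length(vocab) > 400) stop("oracle vocab overflow")
  code <- function(w) intToUtf8(match(w, vocab) + 255L, multiple = FALSE)
  drop(utils::adist(paste(vapply(target_words, code, ""), collapse = ""),
                    paste(vapply(response_words, code, ""), collapse = "")))
}

# Jaro similarity recomputed from the definition with a match matrix.
oracle_jaro <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  if (length(a) == 0 && length(b) == 0) return(0)
  if (length(a) == 0 || length(b) == 0) return(1)
  w <- max(floor(max(length(a), length(b)) / 2) - 1, 0)
  taken <- rep(FALSE, length(b))
  am <- character(0)
  bm_idx <- integer(0)
  for (i in seq_along(a)) {
    lo <- max(1, i - w)
    hi <- min(length(b), i + w)
    if (lo > hi) next
    window <- lo:hi
    hit <- window[!taken[window] & b[window] == a[i]]
    if (length(hit) > 0) {
      taken[hit[1]] <- TRUE
      am <- c(am, a[i])
      bm_idx <- c(bm_idx, hit[1])
    }
  }
  m <- length(am)
  if (m == 0) return(1)
  bm <- b[sort(bm_idx)]
  transpositions <- sum(am != bm) / 2
  1 - (m / length(a) + m / length(b) + (m - transpositions) / m) / 3
}

# Brute-force DTW: enumerate every monotone warping path, track the minimum
# cost and, among minimum-cost paths, the minimum length; return cost/length.
oracle_dtw <- function(a, b) {
  a <- if (length(a) == 1 && is.character(a)) strsplit(a, "")[[1]] else a
  b <- if (length(b) == 1 && is.character(b)) strsplit(b, "")[[1]] else b
  n <- length(a)
  m <- length(b)
  best <- c(cost = Inf, len = Inf)
  recurse <- function(i, j, cost, len) {
    cost <- cost + (a[i] != b[j])
    len <- len + 1
    if (cost > best["cost"]) return(invisible())
    if (i == n && j == m) {
      if (cost < best["cost"] ||
          (cost == best["cost"] && len < best["len"])) {
        best <<- c(cost = cost, len = len)
      }
      return(invisible())
    }
    if (i < n) recurse(i + 1, j, cost, len)
    if (j < m) recurse(i, j + 1, cost, len)
    if (i < n && j < m) recurse(i + 1, j + 1, cost, len)
    invisible()
  }
  recurse(1, 1, 0, 0)
  unname(best["cost"] / best["len"])
}

# All strings of length 1..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  cur <- alphabet
  for (len in seq_len(max_len)) {
    out <- c(out, cur)
    if (len < max_len) {
      cur <- as.vector(outer(cur, alphabet, paste0))
    }
  }
  out
}

random_string <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
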