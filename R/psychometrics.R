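#' Fit psychometric curves to vowel-discrimination responses
#'
#' Fits a fixed-effects logistic regression of the binary diphthong response
#' on NLP condition, morph fraction and voice pitch (in kHz), with the full
#' three-way interaction — the fixed-effects skeleton of the multilevel model
#' `diphthong ~ condition * morph * pitch`. Subject clustering is handled by
#' bootstrap resampling over subjects when confidence intervals are computed
#' (see [threshold50()] and [condition_contrast()]), not by random effects.
#'
#' @param scored Tibble from [score_responses()] on a vowel-experiment
#'   manifest: needs columns `diphthong_response`, `condition`, `morph`,
#'   `f0_hz` and `subject_id`.
#' @param min_cell Minimum number of trials required per condition before a
#'   condition enters the fit (default 50); under-filled cells are dropped
#'   with a warning and flagged in the result.
#' @return An object of class `psychometric_fit`: list with the `glm` model,
#'   the fitting data, and the conditions kept/skipped.
#' @export
fit_psychometric <- function(scored, min_cell = 50) {
  needed <- c("diphthong_response", "condition", "morph", "f0_hz",
              "subject_id")
  if (!all(needed %in% names(scored))) {
    stop("scored data must contain: ", paste(needed, collapse = ", "))
  }
  dat <- scored |>
    dplyr::mutate(pitch_khz = .data$f0_hz / 1000,
                  condition = factor(.data$condition))
  counts <- dplyr::count(dat, .data$condition)
  skipped <- as.character(counts$condition[counts$n < min_cell])
  if (length(skipped) > 0) {
    warning("conditions skipped for insufficient trials: ",
            paste(skipped, collapse = ", "))
    dat <- dat[!(as.character(dat$condition) %in% skipped), , drop = FALSE]
    dat$condition <- droplevels(dat$condition)
  }
  if (nrow(dat) == 0L) stop("no conditions with enough trials to fit")
  model <- stats::glm(
    diphthong_response ~ condition * morph * pitch_khz,
    family = stats::binomial(), data = dat
  )
  structure(list(model = model, data = dat,
                 conditions = levels(dat$condition), skipped = skipped),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit: %d trials, %d subjects, conditions: %s>\n",
              nrow(x$data), dplyr::n_distinct(x$data$subject_id),
              paste(x$conditions, collapse = ", ")))
  if (length(x$skipped)) {
    cat("  skipped (too few trials):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for psychometric fits
#'
#' `tidy()` returns the coefficient table of the underlying logistic model;
#' `glance()` returns one-row model-level summaries.
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' @rdname tidy.psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    n_trials = nrow(x$data),
    n_subjects = dplyr::n_distinct(x$data$subject_id),
    n_conditions = length(x$conditions),
    null.deviance = m$null.deviance,
    deviance = m$deviance,
    AIC = stats::AIC(m)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

# Fitted P(diphthong) at given morph values for one condition x pitch.
predict_curve <- function(fit, condition, pitch_hz, morph) {
  nd <- tibble::tibble(
    condition = factor(condition, levels = fit$conditions),
    morph = morph,
    pitch_khz = pitch_hz / 1000
  )
  as.numeric(stats::predict(fit$model, newdata = nd, type = "response"))
}

# 50% point of one fitted curve: morph where P crosses halfway between the
# fitted floor P(0) and ceiling P(1). Returns NA when unattained (flat or
# non-crossing curve).
curve_threshold50 <- function(p_fun) {
  p0 <- p_fun(0)
  p1 <- p_fun(1)
  if (abs(p1 - p0) < 1e-6) return(NA_real_)  # flat: halfway point undefined
  target <- (p0 + p1) / 2
  f <- function(m) p_fun(m) - target
  # fitted logistic curves are monotone in morph within a cell; still guard
  if (f(0) * f(1) > 0) return(NA_real_)
  stats::uniroot(f, c(0, 1), tol = 1e-6)$root
}

#' 50% discrimination threshold for one condition and pitch
#'
#' The threshold is the amount of morphing that raises the fitted probability
#' of a "diphthong" response halfway from floor (the fitted value at
#' morph = 0) to ceiling (at morph = 1). A 95% confidence interval is
#' obtained by resampling subjects with replacement and refitting. Flat or
#' non-crossing curves are flagged (`NA` threshold with
#' `attained = FALSE`).
#'
#' @param fit A [fit_psychometric()] object.
#' @param condition Condition label present in the fit.
#' @param pitch_hz Voice pitch in Hz at which to evaluate the curve.
#' @param n_boot Bootstrap resamples for the CI (default 199; 0 skips the
#'   CI).
#' @return A one-row tibble: `condition`, `pitch_hz`, `threshold50`,
#'   `ci_lower`, `ci_upper`, `attained`.
#' @export
threshold50 <- function(fit, condition, pitch_hz, n_boot = 199) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!condition %in% fit$conditions) {
    stop("condition not present in the fit: ", condition)
  }
  est <- curve_threshold50(function(m) predict_curve(fit, condition,
                                                     pitch_hz, m))
  lo <- hi <- NA_real_
  if (n_boot > 0 && !is.na(est)) {
    # the fully interacted model factorizes over conditions, so resampled
    # refits only need the queried condition's trials: identical estimand,
    # far cheaper than refitting the full surface every resample
    cond_dat <- fit$data[as.character(fit$data$condition) == condition, ]
    subjects <- unique(cond_dat$subject_id)
    by_subj <- split(cond_dat, cond_dat$subject_id)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      dat <- dplyr::bind_rows(by_subj[as.character(take)])
      m <- tryCatch(
        suppressWarnings(
          stats::glm(diphthong_response ~ morph * pitch_khz,
                     family = stats::binomial(), data = dat)),
        error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      p_fun <- function(mm) {
        nd <- data.frame(morph = mm, pitch_khz = pitch_hz / 1000)
        as.numeric(stats::predict(m, newdata = nd, type = "response"))
      }
      curve_threshold50(p_fun)
    }, numeric(1))
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 20) {
      qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      lo <- qs[1]
      hi <- qs[2]
    }
  }
  tibble::tibble(condition = condition, pitch_hz = pitch_hz,
                 threshold50 = est, ci_lower = lo, ci_upper = hi,
                 attained = !is.na(est))
}

#' Contrast a metric between two conditions with a cluster bootstrap
#'
#' Computes the difference in subject-pooled mean metric between conditions
#' `cond_a` and `cond_b` (A minus B) with a percentile confidence interval
#' from resampling subjects with replacement — the fixed-effects stand-in for
#' posterior condition contrasts.
#'
#' @param scored Tibble of per-trial scores with `subject_id` and `condition`
#'   columns.
#' @param metric Name of the metric column to contrast.
#' @param cond_a,cond_b Condition labels.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `metric`, `cond_a`, `cond_b`, `difference`,
#'   `ci_lower`, `ci_upper`, `n_subjects`.
#' @export
condition_contrast <- function(scored, metric, cond_a, cond_b,
                               n_boot = 2000, conf = 0.95) {
  if (!metric %in% names(scored)) stop("no such metric column: ", metric)
  dat <- scored[scored$condition %in% c(cond_a, cond_b),
                c("subject_id", "condition", metric)]
  names(dat)[3] <- "y"
  if (!all(c(cond_a, cond_b) %in% dat$condition)) {
    stop("both conditions must be observed in the data")
  }
  subjects <- unique(dat$subject_id)
  if (length(subjects) < 2L) {
    stop("cluster bootstrap needs at least 2 subjects")
  }
  diff_fun <- function(d) {
    mean(d$y[d$condition == cond_a]) - mean(d$y[d$condition == cond_b])
  }
  est <- diff_fun(dat)
  by_subj <- split(dat, dat$subject_id)
  boots <- vapply(seq_len(n_boot), function(b) {
    take <- sample(subjects, length(subjects), replace = TRUE)
    d <- dplyr::bind_rows(by_subj[as.character(take)])
    if (!all(c(cond_a, cond_b) %in% d$condition)) return(NA_real_)
    diff_fun(d)
  }, numeric(1))
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(metric = metric, cond_a = cond_a, cond_b = cond_b,
                 difference = est, ci_lower = qs[1], ci_upper = qs[2],
                 n_subjects = length(subjects))
}

#' Plot fitted psychometric curves
#'
#' Draws the fitted probability of a "diphthong" response against morph
#' fraction for each condition, faceted by the requested pitch values, with
#' the observed condition means overlaid.
#'
#' @param object A `psychometric_fit`.
#' @param pitch_hz Pitch values (Hz) at which to draw curves (default the
#'   quartiles of the fitted data).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, pitch_hz = NULL, ...) {
  if (is.null(pitch_hz)) {
    pitch_hz <- round(stats::quantile(object$data$f0_hz, c(0.1, 0.5, 0.9)))
  }
  grid <- tidyr::crossing(
    condition = object$conditions,
    pitch_hz = pitch_hz,
    morph = seq(0, 1, by = 0.02)
  ) |>
    dplyr::mutate(p = purrr::pmap_dbl(
      list(.data$condition, .data$pitch_hz, .data$morph),
      function(c, f, m) predict_curve(object, c, f, m)
    ))
  ggplot2::ggplot(grid, ggplot2::aes(.data$morph, .data$p,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pitch_hz, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "morph fraction", y = "P(diphthong response)",
                  colour = "condition") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
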