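test_that("every manipulation at zero depth or magnitude is the identity", {
  w <- synth_harmonics(constant_track(220, 0.5), 9, SR)
  tr <- constant_track(220, 0.5)
  expect_identical(apply_am(w, 100, 0), w)
  expect_identical(apply_jitter(tr, 0, 1000, SR), tr)
  c0 <- f0_contour(c(0, 1), c(220, 220))
  expect_identical(apply_frequency_jump(c0, 0.5, 0, "up"), c0)
  expect_identical(apply_pitch_shift(c0, 0)$f0_hz, c0$f0_hz)
  # subharmonics at zero depth: same samples as plain harmonic synthesis
  sub0 <- apply_subharmonics(tr, 9, SR, 2L, 0)
  expect_identical(sub0$samples, w$samples)
})

test_that("AM creates sidebands at carrier +/- am_freq with depth/4 level", {
  carrier <- tone(2000, 1)
  am <- apply_am(carrier, 100, 0.5)
  sp <- measure_spectrum(am)
  carrier_amp <- peak_level(sp, 2000)
  # the modulated carrier is attenuated by 1 - depth/2, so sidebands sit at
  # (depth/4) / (1 - depth/2) relative to it
  expected_db <- ratio_to_db((0.5 / 4) / (1 - 0.5 / 2))
  for (side in c(1900, 2100)) {
    side_db <- ratio_to_db(peak_level(sp, side) / carrier_amp)
    expect_lt(abs(side_db - expected_db), 0.5)
  }
  expect_error(apply_am(carrier, 12000, 0.5), "Nyquist")
  expect_error(apply_am(carrier, 100, 1.4), "0, 1")
})

test_that("AM outside episodes leaves the signal untouched", {
  carrier <- tone(500, 1)
  am <- apply_am(carrier, 80, 0.6, episodes = episodes(0.4, 0.6))
  first_part <- seq_len(round(0.3 * SR))
  expect_equal(am$samples[first_part], carrier$samples[first_part])
  mid <- round(0.5 * SR) + seq_len(1000)
  expect_false(isTRUE(all.equal(am$samples[mid], carrier$samples[mid])))
})

test_that("subharmonics insert a peak at f0/ratio and double the period", {
  tr <- constant_track(220)
  w <- apply_subharmonics(tr, 9, SR, 2L, 0.5)
  sp <- measure_spectrum(w)
  # new spectral peak at 110 Hz, absent from plain synthesis
  plain_sp <- measure_spectrum(synth_harmonics(tr, 9, SR))
  expect_gt(peak_level(sp, 110) / peak_level(sp, 220), 0.2)
  expect_lt(peak_level(plain_sp, 110) / peak_level(plain_sp, 220), 1e-3)
  # autocorrelation period becomes 1/110 s
  x <- w$samples
  ac <- stats::acf(x, lag.max = 250, plot = FALSE)$acf[, 1, 1]
  lag110 <- round(SR / 110)
  lag220 <- round(SR / 220)
  expect_gt(ac[lag110 + 1], ac[lag220 + 1])
  expect_error(apply_subharmonics(constant_track(35), 9, SR, 2L, 0.5),
               "20 Hz")
})

test_that("subharmonic partial amplitudes follow depth times the rolloff curve", {
  tr <- constant_track(440)
  depth <- 0.4
  w <- apply_subharmonics(tr, 6, SR, 2L, depth)
  sp <- measure_spectrum(w)
  h1 <- peak_level(sp, 440)
  for (mult in c(0.5, 1.5, 2.5)) {
    expected <- depth * db_to_ratio(-6 * log2(mult))
    expect_equal(peak_level(sp, mult * 440) / h1, expected,
                 tolerance = expected * 0.12)
  }
})

test_that("jitter stays within its semitone bound and scales with depth", {
  set.seed(3)
  tr <- constant_track(220, 45)  # about 1e6 samples
  for (depth in c(2, 4)) {
    j <- apply_jitter(tr, depth, 1000, SR)
    dev_st <- 12 * log2(j / tr)
    expect_lte(max(abs(dev_st)), depth / 2 + 1e-9)
  }
  spread2 <- stats::sd(12 * log2(apply_jitter(tr, 2, 1000, SR) / tr))
  spread4 <- stats::sd(12 * log2(apply_jitter(tr, 4, 1000, SR) / tr))
  expect_gt(spread4, spread2)
  expect_error(apply_jitter(tr, -1, 1000, SR), ">= 0")
})

test_that("sample-and-hold jitter interpolation is available", {
  set.seed(4)
  tr <- constant_track(220, 0.2)
  j <- apply_jitter(tr, 4, 1000, SR, interpolation = "constant")
  # piecewise-constant: long runs of identical values
  expect_gt(mean(diff(j) == 0), 0.9)
})

test_that("alternating jump plans oppose direction and resist drift", {
  c0 <- f0_contour(c(0, 3), c(220, 180))
  set.seed(9)
  plan <- plan_jumps_alternating(c0, 1)
  expect_equal(nrow(plan), 1)
  expect_true(plan$direction %in% c("up", "down"))

  n_rep <- 500
  alt_frac <- numeric(n_rep)
  cum_shift <- numeric(n_rep)
  mean_mag <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(r)
    p <- plan_jumps_alternating(c0, 5, c(0.5, 12))
    signed <- ifelse(p$direction == "up", p$magnitude, -p$magnitude)
    alt_frac[r] <- mean(diff(match(p$direction, c("down", "up"))) != 0)
    cum_shift[r] <- abs(sum(signed))
    mean_mag[r] <- mean(p$magnitude)
  }
  expect_gte(mean(alt_frac), 0.8)
  # anti-drift: mean |cumulative shift| below mean |single jump|
  expect_lt(mean(cum_shift), mean(mean_mag))
})

test_that("jumped contours stay within an octave of the original range", {
  c0 <- f0_contour(c(0, 3), c(220, 180))
  for (r in 1:50) {
    set.seed(r)
    plan <- plan_jumps_alternating(c0, 5, c(0.5, 12))
    jumped <- apply_jump_plan(c0, plan)
    expect_gte(min(jumped$f0_hz), min(c0$f0_hz) / 2)
    expect_lte(max(jumped$f0_hz), max(c0$f0_hz) * 2)
  }
})

test_that("episode placement honours mode, coverage and ordering", {
  expect_equal(place_episodes(3, "continuous"), episodes_continuous())
  for (r in 1:30) {
    set.seed(r)
    eps <- place_episodes(3, "intermittent")
    expect_gte(nrow(eps), 2)
    expect_lte(nrow(eps), 8)
    expect_true(all(eps$start < eps$end))
    expect_true(all(diff(eps$start) > 0))
    # non-overlap
    if (nrow(eps) > 1) {
      expect_true(all(eps$start[-1] >= eps$end[-nrow(eps)]))
    }
    coverage <- sum(eps$end - eps$start)
    expect_gte(coverage, 0.2 - 1e-9)
    expect_lte(coverage, 0.8 + 1e-9)
  }
  expect_error(place_episodes(-1, "intermittent"), "positive")
})

test_that("episode windows validate their shape", {
  expect_error(episodes(c(0.1, 0.3), c(0.4, 0.6)), "overlap")
  expect_error(episodes(0.5, 0.4), "start < end")
  expect_silent(episodes(c(0.1, 0.5), c(0.3, 0.9)))
})
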