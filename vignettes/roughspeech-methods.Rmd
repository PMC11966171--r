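---
title: "Synthesizing and scoring speech with nonlinear vocal phenomena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing and scoring speech with nonlinear vocal phenomena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughspeech)
```

## The problem

Nonlinear vocal phenomena (NLP) — subharmonics, amplitude modulation,
jitter-driven "chaos", abrupt frequency jumps, and whispery aperiodic
phonation — are irregular modes of vocal-fold vibration that make voices
sound rough or harsh. Whether they *degrade* speech intelligibility, or can
even help a listener, is an empirical question that requires precisely
controlled stimuli: the same vowel, word, or sentence rendered with and
without each phenomenon, at controlled pitch and signal-to-noise ratio, and
listener responses scored with well-defined distance metrics.

`roughspeech` implements that entire chain: parametric source–filter
synthesis, source-level NLP manipulations, masking-noise mixing,
reproducible stimulus manifests for three listening-experiment designs,
intelligibility metrics, psychometric fitting, and — so the pipeline is
exercisable without any recordings or human participants — a synthetic
material store and a simulated listener.

## Source–filter synthesis

The voice source is built additively: one continuous sine per harmonic, with
per-harmonic phase accumulated as the cumulative integral of instantaneous
frequency so that slowly varying f0 never produces clicks. Harmonic *k* is
attenuated by `rolloff * log2(k)` dB; the vowel experiment uses 3 dB/octave
(a bright source that exposes formants), and the word/sentence resynthesis
uses a realistic 9 dB/octave plus white noise at −30 dB relative to the
harmonic component. Harmonics stop at the Nyquist frequency minus a 50 Hz
guard band, evaluated at the f0 contour's peak, so pitch maxima never alias.
All synthesis runs at 22 050 Hz.

F0 contours are tibbles of time-stamped anchors with voiced flags.
Interpolation to the sample grid uses a monotone (Fritsch–Carlson) cubic in
log-frequency: smooth inside voiced spans, no overshoot between anchors.
Contours are interpolated piecewise, splitting wherever two anchors sit
closer than 1 ms — that is how frequency jumps survive interpolation as true
discontinuities instead of being smoothed away.

The vocal tract is a frame-wise spectral filter: each STFT frame (1024
samples, 75% overlap, Hann) is multiplied by a gain curve with Lorentzian
resonance peaks at the formant frequencies. This realization was chosen over
a recursive resonator cascade because the same machinery then serves
envelope transplantation; the peak-location contract (recoverable within
±50 Hz on steady segments) holds either way. Formants above F4 are
extrapolated to Nyquist at the vowel's mean formant spacing. The preset
vowel table holds typical adult-male values for /a o e i u/ with bandwidths
`B = 50 + 0.05 F` Hz; the published experiments used values measured from a
single male speaker that are not printed anywhere, so the table is
explicitly a stand-in and user-overridable everywhere.

Diphthongs morph linearly: formant *i* at time fraction τ is
`F_from + τ * morph * (F_to − F_from)`, so `morph = 0` is a static
monophthong and `morph = 1` glides all the way. A compressor (divide by the
50 ms-smoothed Hilbert envelope, floored at 1% of its peak, then rescale to
the input RMS) removes the loudness swings morphing would otherwise cause.

## The NLP manipulations

All manipulations act at the source level, gated by *episode windows*
(fractions of stimulus duration) with 5 ms raised-cosine ramps so the edits
never click:

* **AM** multiplies by `1 − d/2 + (d/2) cos(2π f t)`: `d` is the
  peak-to-trough fraction, so sidebands appear at ±`f` around each partial
  at `d/4` of its amplitude. The term "depth" has no standard definition for
  these effects; this reading, and the subharmonic one below, are the
  package's documented choices and both are plain scalars so alternative
  readings can be tested.
* **Subharmonics** insert partials at `m·f0/ratio` (m not divisible by
  `ratio`), each at `depth` times the rolloff curve evaluated at that
  frequency; period doubling (`ratio = 2`) adds f0/2, 3f0/2, … and doubles
  the waveform period.
* **Chaos** is emulated as rapid jitter: f0 multiplied by `2^(u(t)/12)`,
  `u(t)` uniform in ±depth/2 semitones, resampled at 1 kHz and linearly
  interpolated (sample-and-hold available behind a flag). The perturbation
  is hard-bounded by depth/2 semitones. True deterministic-chaos modelling
  is deliberately out of scope.
* **Frequency jumps** multiply every anchor after a chosen point by
  `2^(±st/12)`, preserving the discontinuity exactly. For sentences, about
  five jumps are planned with directions that oppose the previous jump with
  probability 0.9 — and are forced to oppose the running total whenever it
  would leave ±12 st — keeping the contour within an octave of its original
  range.
* **Whisper** replaces the source with Gaussian white noise (no harmonic
  component). In the intermittent sentence condition, whisper is crossfaded
  in per episode at matched RMS.

Episode placement for intermittent conditions draws the episode count from a
Poisson(5) truncated to [2, 8] and total coverage uniform in 20–80% of the
stimulus; the stated design says only "about five separate episodes", so
these two distributions are package choices, fixed once and documented here.
In the mixed condition each episode independently gets AM, subharmonics or
chaos, on top of the frequency jumps.

## Noise, mixing, manifests

Masking noise is constructed in the frequency domain — flat to 1.2 kHz,
−6 dB/kHz above — with random phases per frame, then inverse-STFTed.
Signal and noise are mixed after RMS normalization so that
`20 log10(RMS_s/RMS_n)` equals the target SNR, then peak-normalized. RMS is
computed over the full duration; a voice-active-frames option was considered
and rejected as the default because the stimuli have little silence.

The three manifests are pure functions of a seed (re-running yields
byte-identical CSV):

* **Vowels**: 999 prototypes (f0 log-uniform 110–880 Hz, 50% diphthongs
  with morph in {0.1…1.0}, 700 ms) × 5 conditions = 4995 stimuli. The
  published realization had 480/519 diphthongs/monophthongs; the manifest
  reproduces the 50% rule, not that particular draw.
* **Words**: 1300 six-digit sequences (digits 1–9; zero excluded), each
  assigned uniformly to one of 6 NLP × 3 pitch = 18 cells (whispered stimuli
  carry no pitch shift since they have no f0), SNR uniform in [−6, 15] dB.
  Uniform cell assignment is a choice; the design is described only as
  "randomly chosen".
* **Sentences**: 100 sentences × 12 conditions = 1200 stimuli; the noise
  arm (0 dB SNR) is applied at presentation, not in the manifest. The
  original corpus is external; four printed example sentences ship verbatim
  and the remaining 96 are deterministic synthetic word strings.

Per-record seeds derive from `(master seed, row index)` via a fixed affine
map mod 2³¹, so any single stimulus is reproducible from its manifest row
alone.

## Synthetic material and the simulated listener

The material store stands in for the recorded corpora: eight speaker
profiles (four male at 100–140 Hz base f0, four female at 180–240 Hz, with
formant scale factors), per-speaker digit tokens of 0.40–0.56 s (so
six-digit sequences with 50–200 ms pauses land in the attested 2.6–4.4 s
range), and sentence plans with word durations of 0.20–0.36 s. Spectral and
amplitude envelopes are constructed parametrically from per-token formant
sets and attack–sustain–release shapes on the same time–frequency grid the
envelope extractor uses, then transplanted onto the NLP-manipulated sources
exactly as extracted envelopes would be.

The simulated listener is deliberately simple and labelled illustrative:

* Vowel task: P("diphthong") is a lapse-mixed logistic in morph whose
  midpoint rises linearly with pitch — fastest in the condition without NLP
  — plus Gaussian subject intercepts (s.d. 0.3 logits, lapse 0.02). The
  default midpoint-rise ordering (tonal ≫ AM > subharmonics > chaos >
  whisper) mirrors the qualitative result pattern, not any fitted value.
* Word task: each digit is independently misheard with probability from a
  logistic in SNR (slope −0.18 per dB) shifted per condition and pitch;
  wrong digits are uniform over the other eight (no phonetic-confusability
  model — a documented simplification).
* Sentence task: each word is independently deleted or substituted with a
  per-condition, per-noise-arm probability whose defaults qualitatively
  mirror the reported pattern (whisper/jumps/mixed collapsing under noise,
  AM and subharmonics benign).

What passing tests show, therefore, is that the pipeline's *machinery* is
correct — synthesis obeys its spectral contracts, manifests reproduce the
design exactly, metrics equal their oracles, and the estimators recover
known parameters. They do not show anything about real listeners: human
effect sizes require the deposited response data and are out of scope.

## Estimation

The published analyses used Bayesian multilevel models. Those are replaced
here — by design, not approximation of priors — with fixed-effects fits
plus subject-cluster bootstrap: the logistic
`response ~ condition * morph * pitch` for the vowel task, and plain
condition contrasts of per-trial metrics elsewhere. The fully interacted
logistic factorizes over conditions, which the threshold bootstrap exploits
by refitting only the queried condition's trials per resample.

The 50% discrimination threshold is the morph value where the fitted curve
crosses halfway between its value at morph 0 (floor) and morph 1 (ceiling),
found by `uniroot` on [0, 1]; flat or non-crossing curves are flagged
unattained rather than extrapolated. CIs are percentile intervals over
subjects resampled with replacement (199 resamples by default for
thresholds, 2000 for contrasts).

Scoring: digit sequences are compared positionally (0–6 errors; short
responses pad as errors) and by symbol-level DTW with 0/1 local cost,
normalized by warping-path length — among minimum-cost paths the shortest,
making the quantity well-defined; the normalization divisor is unstated in
the design and this choice is recorded here. Sentences are normalized
(lower-case, alphanumerics and single spaces), then scored by WER (clamped
to 1 so accuracy stays in [0, 1]), character-level Levenshtein normalized by
target length, and Jaro distance with the standard window and
half-transposition count. Response times may be adjusted by subtracting
stimulus duration; negative adjusted RTs are legitimate because responding
can begin during playback.

## Numerical choices and degenerate inputs

* STFT: 1024-point Hann, hop 256 (COLA-compliant); inverse by weighted
  overlap-add with a 10⁻⁸ floor on the window-energy normalizer.
* Envelope smoothing: 300 Hz frequency kernel, 200 ms time window, matching
  the stated extraction parameters; transplantation rejects duration
  mismatches beyond 10% and floors the whitening divisor at 10⁻⁶ of the
  spectral peak.
* Compressor floor: 1% of envelope peak, preventing noise blow-up in
  silences.
* Silent inputs error out of `add_source_noise`, `extract_envelopes`,
  `compress_dynamics` and `mix_at_snr` (the implied ratios are undefined).
* Subharmonics below 20 Hz, formants at or above Nyquist, f0 at Nyquist,
  and pitch shifts beyond 3000 Hz are rejected.
* Harmonic phases start at 0 (deterministic); a seedable random-phase
  option exists but is off by default.
* Whether source noise should be spectrally shaped before filtering is
  unspecified in the design; white noise is used, literally.

## Problem sizes used in validation

The test-suite and acceptance script run at desk scale, chosen so the whole
suite completes in minutes: metric–oracle equivalence is exhaustive for all
string pairs up to length 3 over a 3-symbol alphabet plus thousands of
seeded pairs up to length 8 (the DTW brute-force oracle enumerates every
warping path, which is why its sampled pairs stop at length 6); threshold
recovery uses 40 simulated listeners × 200 trials per replicate, 100
replicates in the test suite and 20 in the acceptance script, with
199-resample bootstrap CIs. Audio checks use 1–4 s test signals.

## Known limitations

* The vowel formant presets, sentence corpus beyond the four printed
  examples, and all listener-model parameters are synthetic stand-ins;
  condition effect sizes produced by the simulator are illustrative only.
* "Chaos" is jitter, not a chaotic oscillator; jitter perturbs f0 only, not
  harmonic amplitudes.
* The compressor, filter and transplantation operate on magnitude spectra;
  phase is inherited from the source, so transplantation is not an exact
  inverse of extraction.
* RT modelling beyond duration adjustment, and any reproduction of the
  published credible intervals, are out of scope.
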