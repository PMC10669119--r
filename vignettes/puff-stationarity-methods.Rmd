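---
title: "Methods: characterizing gradient-switching artifact puffs and testing their stationarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing gradient-switching artifact puffs and testing their stationarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffstat)
```

## The problem

Switching magnetic-field gradients during MRI induces voltages on any
electrodes inside the bore. On broadband electrophysiological channels
(bandwidth above ~150 Hz) these induced potentials are large, fall inside
the signal band, and cannot simply be filtered out. They arrive as short
oscillatory bursts — *artefact puffs* — recurring pseudo-periodically at
the sequence's repetition rate, and their overall amplitude is slowly
modulated by low-frequency environmental noise. Filter design for
artifact removal depends on whether this contamination can be treated as
(wide-sense) stationary, and at which time scale. `puffstat` implements
the two complementary analyses this question calls for:

* a **global** analysis of a multi-second recording, and
* a **local** analysis of each extracted puff,

each combining time-domain features (RMS, mean puff, normalized MSE),
frequency-domain features (Welch-WOSA PSD and its moments), the **KPSS**
stationarity test, and a **surrogate-based time-frequency** stationarity
test with an index of non-stationarity (INS).

## The synthetic generator

No public recordings of isolated gradient-induced potentials exist, so
the package ships a generator whose output has the statistical structure
the analyses assume, plus ground-truth puff boundaries so every stage is
testable. A recording is

    x(t) = A(t) * sum_k a_k p(t - t_k)  +  baseline(t)  +  noise(t),

low-pass filtered at the end:

* `p(t) = exp(-decay t) cos(2 pi f_c t)` on `[0, puff_duration)` — an
  exponentially damped cosine burst. The real puff waveform is not
  specified by any physical model we implement; the damped cosine is a
  stand-in for an oscillatory transient, and the template family is the
  one place a user would substitute their own shape.
* onsets `t_k = k * puff_period + jitter_k`, with Gaussian jitter
  truncated at `puff_period / 4` so intervals stay disjoint.
* `A(t) = 1 + am_depth * sin(2 pi f_am t)` — the multiplicative
  low-frequency amplitude modulation seen on bench recordings; an
  additive slow baseline (sinusoid plus heavily smoothed noise) is
  available behind the `baseline` flag and off by default.
* white Gaussian noise of standard deviation `noise_sd`, and a
  zero-phase 4th-order Butterworth low-pass at 350 Hz emulating a
  broadband acquisition channel.

Defaults are fixed at the bench conditions the package targets: 5 kHz
sampling, 10 s duration, one puff per 62.5 ms (80 puffs per 5 s). Six
presets (`sequence_preset()`) span two sequence families by three slice
orientations: FSE-like puffs last 30 ms; CINE-like puffs last 8 ms —
short enough that the time-frequency test cannot run on single puffs,
which is deliberate: it reproduces the practical failure mode of the
method on very short transients. Carrier frequencies (250/90/140 Hz
FSE-like; 225/275/234 Hz CINE-like) sit in the distinct per-orientation
bands reported for such recordings, all below the 350 Hz channel. The
decay constant is `2 / puff_duration`, so a burst decays to ~13 % of its
peak by its end: clearly extinguishing, but with a tail that a
segmentation method must work to recover. `am_depth` 0.3 (FSE-like) /
0.2 (CINE-like) at ~1 Hz makes the weakest puffs 30 % smaller than the
strongest — a visible but not pathological modulation; `noise_sd = 0.1`
gives a ~20 dB burst-to-floor ratio.

What the generator does **not** emulate: RF-pulse and magnetohydrodynamic
voltage components, eddy-current tails, inter-puff waveform changes tied
to the actual gradient program, or non-Gaussian noise. Passing tests on
synthetic data therefore show that the pipeline recovers what it assumes;
they do not certify behavior on real bench data beyond those assumptions.

## Normalization and puff extraction

Recordings are Z-scored (`zscore()`), using the sample (n−1) standard
deviation — the convention must be fixed somewhere, and the sample SD is
what `stats::sd` computes; at the lengths involved the distinction is
far below every tolerance in the package.

Reference puff boundaries are manual in practice; `segment_puffs()` is
an automatic stand-in with an exportable result (the annotation format
round-trips, so automatic output can be hand-corrected and re-imported).
It is a double-threshold envelope detector:

1. centered moving-RMS envelope (default window 5 ms);
2. burst *cores* where the envelope exceeds `median + threshold_k * MAD`
   (robust location/scale, because the bursts dominate non-robust
   moments; default `threshold_k = 1.5` — at a ~50 % duty cycle the
   envelope median already sits well above the noise floor, so a large
   multiplier would miss the weakest, AM-attenuated puffs);
3. Schmitt-trigger extension of each core down to a noise-floor
   threshold (10th envelope percentile + `extend_k` times the MAD of the
   sub-median envelope), which recovers the decaying burst tails that a
   single threshold clips;
4. boundary compensation by half the envelope window (a centered
   moving-RMS widens every burst's support by w/2 per side), merging of
   gaps under `min_gap` and removal of intervals under `min_duration`
   (both 5 ms by default).

On the FSE-like preset at low noise this recovers the ground-truth count
exactly with per-puff Jaccard overlap ≥ 0.8 and mean boundary error well
under the envelope window (these are the recovery checks in the test
suite). A single-threshold variant was evaluated first and rejected: it
either missed weak puffs (high threshold) or truncated tails (any
threshold above the noise floor).

## Features

* `rms(x) = sqrt(mean(x^2))`.
* `mean_puff()` resamples every puff to a common grid (median length by
  default) by Fourier (band-limited) interpolation — linear
  interpolation is available as a flag — and averages pointwise.
* `puff_mse()` measures morphology deviation:
  `sum((p_i - m_i)^2) / (N * range(m)^2)`. Normalizing by the squared
  peak-to-peak range of the mean curve makes the quantity dimensionless
  and invariant to a common rescaling of puff and mean curve, which is
  the property one wants when comparing normalized recordings; a
  variant normalizing by the mean-curve average (not scale-invariant) is
  kept behind `normalization = "mean"` for comparability with that
  convention.
* `welch_psd()` is a standard Welch-WOSA estimator: Hamming window, 50 %
  overlap, one-sided density scaled so the integral approximates the
  signal power. Default segment length is 4096 samples for global
  spectra (~1.2 Hz resolution at 5 kHz); per-puff spectra use a single
  segment of the puff length (a modified periodogram), with no zero
  padding. None of these choices is canonical; they are the ones a
  practitioner would reach for and they are all exposed.
* `spectral_params()` reports power-weighted moments on the discrete
  grid: mean frequency, maximum-amplitude frequency and spectral
  standard deviation, all in Hz. Reported per-puff spectral SDs are
  therefore tens of Hz; conventions that normalize frequency to [0, 1]
  would give values three orders of magnitude smaller for the same
  spectra, which is worth remembering when comparing across reports.

## The KPSS test

The null hypothesis is stationarity in level (`eta_mu`) or around a
linear trend (`eta_tau`). With residuals `e_t` from the corresponding
regression, partial sums `S_t`, and a Bartlett-kernel long-run variance
`s^2` with bandwidth `nlags`:

    statistic = T^-2 * sum_t S_t^2 / s^2.

Defaults: trend variant — the classical decision threshold 0.1460 used
for the global recordings is the trend-variant asymptotic critical value
at alpha = 0.05 — and Newey-West bandwidth `floor(4 (T/100)^0.25)`
(nothing in the application dictates a bandwidth; this is the standard
default). Decisions use strict `<` at the threshold: an exactly-critical
statistic rejects. `kpss_critical_value_mc()` re-derives critical values
by simulating the white-noise null (with `nlags = 0`, since white noise
needs no long-run correction) and taking the empirical quantile; at
T = 2000 with 50,000 replicates it reproduces 0.146 to within Monte-Carlo
error (the finite-sample value is ~0.148, about 1 % above the
asymptotic one), and the implied type-I error at the 0.146 threshold is
5 % within ±1 %.

## The time-frequency stationarity test

Stationarity over an observation horizon is identified with "all local
spectra look like the global spectrum". The machinery:

1. **Multitaper Hermite spectrogram** (`hermite_bank()`,
   `mt_spectrogram()`): the average of K spectrograms using the first K
   Hermite functions as windows (sampled on `[-6, 6]`, QR-orthonormalized
   so the discrete Gram matrix is the identity to machine precision).
   K = 5 by default. The window length is `odd(round(win_frac * n))`
   with `win_frac` in 0.03–0.075 of the analyzed signal — the window
   *fraction* is the method's intrinsic degree of freedom, setting the
   local horizon relative to the global one. Analysis times are spaced
   by half the window length (the window length is taken as the
   equivalent width); they stay inside the fully supported range, and
   explicitly requested edge positions use zero extension.
2. **Surrogates** (`make_surrogates()`): stationarized references that
   keep the signal's DFT modulus exactly and randomize the phase
   uniformly on [-pi, pi] (Hermitian symmetry enforced; DC and Nyquist
   kept real). Each surrogate uses a seed derived from the master seed
   and its index, so surrogate j is reproducible regardless of J.
3. **Distances** (`spectral_distance()`): symmetric (Jeffreys)
   Kullback-Leibler divergence of unit-sum-normalized spectra times
   `(1 + mean |log G/H|)` of the raw spectra; bins floored at 1e-12 of
   each spectrum's maximum before logs. `local_global_distances()`
   applies it between each local spectrum and the time marginal.
4. **Statistic and null** (`theta_statistic()`,
   `test_stationarity()`): theta is the population variance over time of
   those divergences; theta1 comes from the signal, theta0(j) from each
   surrogate. A gamma distribution is fitted to {theta0} by maximum
   likelihood (method-of-moments start, fitted on mean-scaled values for
   numerical robustness; if the fit fails the empirical quantile is used
   with a warning), and the threshold is its 1 - alpha quantile. The
   test is one-sided: non-stationary iff theta1 > threshold.
5. **INS**: reported as `sqrt(theta1 / mean(theta0))`, which is ~1 for
   stationary signals and directly comparable with its threshold
   `sqrt(gamma / mean(theta0))`; the plain ratio without the square root
   is available via `sqrt_ins = FALSE`. The square-root convention is
   the one under which published INS thresholds of order 1.3–1.6 are
   interpretable.

Under a white-noise null with J = 50 surrogates the measured level is
~6 % at alpha = 0.05 (the gamma tail is very slightly lighter than the
empirical null's); with full-record amplitude-modulated noise the test
rejects in ≥ 95 % of runs at the same settings, and decisions are stable
between J = 50 and J = 5000. These rates are computed in the test suite,
at signal length 1024; the J = 5000 stability checks run at length 512
to keep the suite fast.

Note that on the synthetic *puff-train* presets the global
time-frequency verdict is data-dependent: pronounced amplitude
modulation and strictly periodic bursts are genuine spectral
nonstationarities at sub-second horizons, and the test may flag them
even when a several-second bench recording of the same nominal character
tests stationary. The package reports what the statistic sees.

### Per-puff analysis and short puffs

For the local analysis every puff is tested individually. A window must
satisfy `Nh > 4K`, so with K = 5 a puff needs at least ~105 samples at
the default per-puff `win_frac = 0.2`. FSE-like puffs (150 samples)
qualify; CINE-like puffs (40 samples) do not, and the study driver marks
them `not-computable` with the reason, while KPSS (which only needs
T ≥ 10) is still reported. The per-puff window fraction is configured
separately (`tf$puff_win_frac`) from the global list because a fraction
of a 150-sample puff and of a 25,000-sample recording are different
physical horizons.

## The study driver

`run_study()` takes a `study_config()` — by default the six synthetic
presets — crops each recording to the first `analysis_window` seconds
(default 5), normalizes, runs the global analyses, extracts puffs
(automatic, annotated, or ground truth), runs the per-puff analyses, and
aggregates min–max and mean–stdev per measure into formatted report
tables (written as TSV plus full-precision JSON). Failures are recorded
per item and do not abort the study, so one malformed input or one
too-short puff cannot take down a six-recording run. Every stochastic
stage derives its stream from the master seed: a rerun of the same
configuration is bit-identical.

Default study parameters are J = 5000 surrogates, K = 5 windows, window
fractions {0.03, 0.04, 0.05, 0.07, 0.075}, alpha = 0.05. The examples in
the README and the test suite use smaller J (20–50) and shorter windows;
decisions are already stable there, as the J-robustness checks show.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open `[start, end)` everywhere, in samples.
* Recordings round-trip through text at 15 significant digits; report
  JSON uses 17 (exact for doubles).
* Constant signals are rejected by `zscore` (sd = 0); zero-mass spectra
  by `spectral_params` and `spectral_distance`; an all-zero spectrogram
  yields zero divergences (a constant-in-time spectrogram is the
  definition of "no evolution").
* Gamma-fit failure falls back to the empirical quantile with a warning
  rather than an error.
* Seeds are 32-bit integers throughout; derived streams use a fixed
  integer hash of (master, index).

## Known limitations

* The puff template is a stand-in, not physics; real CINE/FSE waveforms
  differ in detail.
* The automatic segmenter is calibrated for burst-above-floor envelopes;
  recordings whose baseline wanders faster than the envelope window need
  high-pass pre-filtering first.
* The time-frequency test needs on the order of 100+ samples per
  analysis window to be meaningful; single short transients are out of
  its reach by construction.
* Table-style outputs aggregate with plain means/SDs; no multiple-testing
  correction is applied across puffs (the per-puff decisions are meant as
  descriptive maps of where non-stationarity concentrates).
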